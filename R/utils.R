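## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

## stop() wrapper that keeps the call out of the message
abort <- function(..., class = "scalenorm_error") {
  stop(errorCondition(paste0(...), class = c(class, "error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## deterministic substream seed derived from a root seed and a stage label.
## Exact in double arithmetic (values stay far below 2^53) and reduced into
## the 32-bit range R's RNG seeds accept.
substream_seed <- function(root, label) {
  stopifnot(is_scalar_number(root))
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(root) * 48271 + h) %% 2147483629 + 1)
}

## format "n of m" style messages
plural <- function(n, word) paste0(n, " ", word, if (n != 1) "s")
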