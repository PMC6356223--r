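# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
norm_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

# stop() with a consistent prefix so pipeline errors name their stage
stop2 <- function(...) stop(..., call. = FALSE)

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop2(name, " must be TRUE or FALSE")
  x
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop2(name, " must be a single integer >= ", min)
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop2(name, " must be a probability in [0, 1]")
  as.numeric(x)
}

# quartiles under the linear-interpolation convention where the p-quantile of
# sorted x sits at position p*(n-1); identical to stats::quantile type 7
quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.75), names = FALSE, type = 7)
}
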