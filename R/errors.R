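# Classed conditions so callers can distinguish failure modes programmatically.

cs_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cardiosleep_error"),
                      call = call))
}

cs_assert <- function(cond, msg, class) {
  if (!isTRUE(cond)) cs_error(msg, class, call = sys.call(-1))
  invisible(TRUE)
}

# population standard deviation (n divisor); used everywhere a segment SD
# enters a threshold so results are reproducible bit-for-bit
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# run expression with a private RNG stream; global .Random.seed restored
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
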