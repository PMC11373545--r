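`%||%` <- function(a, b) if (is.null(a)) b else a

# Package-level logger. Stages report dropped-record counts etc. through
# this so they can be silenced with options(protmr.verbose = FALSE).
pm_log <- function(...) {
  if (isTRUE(getOption("protmr.verbose", TRUE))) {
    message("[protmr] ", ...)
  }
  invisible(NULL)
}

pm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "protmr_error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    pm_stop(sprintf("'%s' must be a single finite number", name),
            "protmr_domain_error")
  }
  ok_lo <- if (open_lower) x > lower else x >= lower
  ok_hi <- if (open_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    pm_stop(sprintf("'%s' = %g is outside its valid range", name, x),
            "protmr_domain_error")
  }
  invisible(x)
}

# Derive a stream-specific seed from a root seed so that legs of a
# simulation are independent yet reproducible. A multiply-xor integer
# hash decorrelates the derived seeds: a plain linear map would put them
# on a lattice, and linearly related seeds are a known hazard for RNG
# initialization. Result kept below 2^31 - 1.
split_seed <- function(seed, stream) {
  x <- (as.double(seed) %% 2147483647) * 2654435761 + stream * 40503
  x <- x %% 4294967296
  x <- bitwXor(as.integer(x %% 2147483647),
               as.integer(x %/% 65536))
  x <- (as.double(x) * 2246822519) %% 4294967296
  x <- bitwXor(as.integer(x %% 2147483647),
               as.integer(x %/% 8192))
  abs(x) %% 2147483647
}

two_sided_p <- function(z) 2 * pnorm(-abs(z))
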