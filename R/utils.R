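#' @keywords internal
"_PACKAGE"

#' @import stats
#' @importFrom utils read.csv write.csv read.delim write.table
NULL

# Clip numeric values into [lo, hi]; attaches the number of clipped entries.
clip01 <- function(x, lo = 0, hi = 1) {
  n_clipped <- sum(x < lo | x > hi, na.rm = TRUE)
  x[x < lo] <- lo
  x[x > hi] <- hi
  attr(x, "n_clipped") <- n_clipped
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_neoclocks <- function(..., class = "neoclocks_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
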