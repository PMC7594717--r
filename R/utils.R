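#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim nlminb qchisq rnorm runif setNames lm coef vcov
#'   pchisq sd quantile dbinom
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

emu_key <- function(met, atoms) paste0(met, "|", paste(atoms, collapse = ","))

stop2 <- function(...) stop(..., call. = FALSE)

# popcount for small integers (isotopomer mass from bit pattern)
bit_count <- function(x) {
  n <- 0L
  while (any(x > 0L)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}
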