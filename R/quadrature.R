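# Fixed-order Gauss-Legendre rules, cached per order. Nodes/weights come from
# the Golub-Welsch eigen-decomposition of the Jacobi matrix; exact for
# polynomials up to degree 2n-1 and spectrally accurate for the analytic
# integrands used throughout (all singular chord integrals are removed by a
# trigonometric substitution before quadrature).
.ml_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  rule <- .ml_cache[[key]]
  if (!is.null(rule)) return(rule)
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  rule <- list(x = e$values, w = 2 * e$vectors[1L, ]^2)
  .ml_cache[[key]] <- rule
  rule
}
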