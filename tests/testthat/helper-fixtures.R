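# Shared fixtures built in code.

# reference five-point paired dataset used across regression tests
five_pairs <- function() {
  paired_dataset(plasma = c(1, 2, 3, 4, 5),
                 saliva = c(1.2, 2.1, 2.9, 4.2, 4.8))
}

# bivariate normal pairs with correlation rho, identity true line
rho_pairs <- function(n, rho, mu = 0, sd = 1) {
  x <- rnorm(n, mu, sd)
  y <- mu + rho * (x - mu) + rnorm(n, 0, sd * sqrt(1 - rho^2))
  paired_dataset(x, y)
}

random_phase_od <- function(n = 1) {
  phase_od(od220 = runif(n, 0.2, 2), od232 = runif(n, 0, 2),
           od278 = runif(n, 0, 2), od400 = runif(n, 0, 2))
}

# brute-force re-evaluation of the printed formulas, independent of the
# package's code path
brute_lpo <- function(up, lo) {
  list(dc = (up$od232 / up$od220 + lo$od232 / lo$od220) * 0.14,
       tc = (up$od278 / up$od220 + lo$od278 / lo$od220) * 0.16,
       sb = (up$od400 / up$od220 + lo$od400 / lo$od220) * 52)
}
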