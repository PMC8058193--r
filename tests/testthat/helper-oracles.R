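# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately implemented through different routes than the package
# internals: stiff ODE integration (deSolve), adaptive quadrature
# (stats::integrate) and direct summation.

# a representative arterial input used across tests
ref_feng <- function() {
  feng_input(A1 = 3000, A2 = 40, A3 = 25,
             lam1 = 4, lam2 = 0.6, lam3 = 0.01, tau = 0.2)
}

# stiff numeric solution of the two-tissue transport ODEs
ode_tissue <- function(kin, input, times, rtol = 1e-10, atol = 1e-12) {
  rhs <- function(t, y, parms) {
    ca <- eval_feng(input, t)
    list(c(kin[["K1"]] * ca - (kin[["k2"]] + kin[["k3"]]) * y[1] +
             kin[["k4"]] * y[2],
           kin[["k3"]] * y[1] - kin[["k4"]] * y[2]))
  }
  stopifnot(all(diff(times) > 0), all(times > 0))
  out <- deSolve::lsoda(c(0, 0), c(0, times), rhs, NULL,
                        rtol = rtol, atol = atol)
  unname(rowSums(out[-1, 2:3, drop = FALSE]))
}

# brute-force nested quadrature of the regional model for one frame
quad_region_frame <- function(p, input, t1, t2) {
  b <- p[["k2"]] + p[["k3"]]
  ki <- p[["K1"]] * p[["k3"]] / b
  inner <- function(T) {
    i1 <- stats::integrate(function(u) eval_feng(input, u), 0, T,
                           rel.tol = 1e-11, subdivisions = 2000)$value
    cv <- stats::integrate(function(u) eval_feng(input, u) *
                             exp(-b * (T - u)), 0, T,
                           rel.tol = 1e-11, subdivisions = 2000)$value
    (1 - p[["TBV"]]) * (ki * i1 + p[["K1"]] * p[["k2"]] / b * cv) +
      p[["TBV"]] * eval_feng(input, T)
  }
  stats::integrate(Vectorize(inner), t1, t2, rel.tol = 1e-9)$value / (t2 - t1)
}

# random valid two-tissue parameter draws (reversible allowed)
random_kinetics <- function(n, seed, k4_max = 0.1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    two_tissue_params(runif(1, 0.05, 1), runif(1, 0.05, 1.5),
                      runif(1, 0.01, 0.5), runif(1, 0, k4_max)))
}

rel_err <- function(x, ref, floor = 1e-12) {
  max(abs(x - ref) / pmax(abs(ref), floor))
}
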