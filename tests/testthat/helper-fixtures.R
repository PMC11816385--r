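# Shared fixtures and independent oracles.

R_GAS <- 8.31446

table1 <- bw_compounds()

pair_of <- function(a, b) binary_pair(compound(table1, a), compound(table1, b))

# Independent oracle: bisection root-solve of the implicit equilibrium
# relation 1/T = 1/Tm - (R/dHm) log(x) - (zw/dHm)(1/T)(1-x)^2, never the
# closed form under test.
oracle_branch_t <- function(tm, dhm, x, zw = 0) {
  f <- function(tt) 1 / tt - 1 / tm + (R_GAS / dhm) * log(x) +
    (zw / dhm) * (1 / tt) * (1 - x)^2
  stats::uniroot(f, c(1, 5000), tol = 1e-13)$root
}

# residual of the implicit relation at a claimed temperature
implicit_residual <- function(tt, tm, dhm, x, zw) {
  1 / tt - 1 / tm + (R_GAS / dhm) * log(x) + (zw / dhm) * (1 / tt) * (1 - x)^2
}

# central finite difference of a scalar function
central_diff <- function(f, at, h) (f(at + h) - f(at - h)) / (2 * h)
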