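# Small fixtures shared across test files; everything is generated in code.

single_node <- function(eta = -1.6, tau = 10, ...) {
  vep_model(matrix(0, 1, 1), excitability = eta, tau = tau, ...)
}

# an uncoupled 3-region model with one seizing region
three_nodes <- function(K = 0, ...) {
  C <- matrix(c(0, 0.5, 0.2,
                0.5, 0, 1.0,
                0.2, 1.0, 0), 3, 3)
  vep_model(C, excitability = c(-1.6, -2.5, -3.5), coupling = K, ...)
}

unit_box <- function(d) list(lower = rep(0, d), upper = rep(1, d))

sphere_fn <- function(x) sum((x - 0.3)^2)

rastrigin_fn <- function(x) {
  10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))
}
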