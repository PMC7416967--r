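# one calibrated model shared across test files
.test_env <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.test_env$model)) .test_env$model <- vsm_model()
  .test_env$model
}

test_params <- function() test_model()$params

# reference trajectory of the elevated-matrix-calcium scenario, computed once
test_reference <- function() {
  if (is.null(.test_env$ref))
    .test_env$ref <- reference_run(test_model())
  .test_env$ref
}

# explicit four-state generator matrices used as oracles for the reduced
# gating right-hand sides (rates as documented for each scheme)
ip3r_generator <- function(ca, ip3, p) {
  k1 <- p$b1 / (p$a1 * ip3); k3 <- p$b3 / (p$a3 * ip3)
  # states in order X00, X01, X10, X11
  Q <- matrix(0, 4, 4)
  Q[1, 3] <- p$a5 * ca / (1 + k1)              # X00 -> X10
  Q[3, 1] <- p$b5
  Q[1, 2] <- (p$a2 + p$a4 * k1) * ca / (1 + k1) # X00 -> X01
  Q[2, 1] <- (p$b2 + p$b4 * k3) / (1 + k3)
  Q[3, 4] <- p$a2 * ca                          # X10 -> X11
  Q[4, 3] <- p$b2
  Q[2, 4] <- p$a5 * ca / (1 + k3)               # X01 -> X11
  Q[4, 2] <- p$b5
  diag(Q) <- -rowSums(Q)
  Q
}

ryr_generator <- function(ca, p) {
  # states in order R00, R10, R11, R01
  ka <- p$Kr1 * ca^2; ki <- p$Kr2 * ca
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- ka; Q[2, 1] <- p$Kmr1
  Q[2, 3] <- ki; Q[3, 2] <- p$Kmr2
  Q[1, 4] <- ki; Q[4, 1] <- p$Kmr2
  Q[4, 3] <- ka; Q[3, 4] <- p$Kmr1
  diag(Q) <- -rowSums(Q)
  Q
}

# stationary distribution of a generator matrix
stationary <- function(Q) {
  A <- rbind(t(Q), rep(1, nrow(Q)))
  b <- c(rep(0, nrow(Q)), 1)
  qr.solve(A, b)
}
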