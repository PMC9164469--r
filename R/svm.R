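# In-package linear-kernel SVM.
#
# The classifier is a soft-margin hinge-loss linear SVM with the libsvm
# default cost C = 1 and no other hyperparameters, fit by dual coordinate
# descent (compiled; see src/dcd_svm.cpp).  Columns are centered internally
# (a pure numerical-conditioning step -- the stored column means are folded
# back into the intercept, and no scaling of the data is performed) and the
# bias enters as an augmented constant feature.

fit_linear_svm <- function(x, y01, cost = 1, max_epochs = 1000L,
                           tol = 0.01) {
  stopifnot(is.matrix(x), length(y01) == nrow(x))
  y <- ifelse(y01 == 1L, 1, -1)
  mu <- colMeans(x)
  xc <- cbind(sweep(x, 2L, mu, "-"), bias = 1)
  fit <- dcd_linear_svm(xc, y, cost, as.integer(max_epochs), tol,
                        perm_seed = 88172645L)
  d <- ncol(x)
  w <- fit$w[seq_len(d)]
  b <- fit$w[d + 1L] - sum(w * mu)
  list(w = w, b = b, cost = cost, epochs = fit$epochs,
       converged = fit$converged)
}

decision_linear_svm <- function(fit, x) {
  drop(x %*% fit$w) + fit$b
}
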