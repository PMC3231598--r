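# ---- multilayer perceptron internals -------------------------------------
#
# One hidden layer: sizes p (inputs) -> H (hidden) -> q (outputs). The
# parameter vector theta stacks [vec(W1) (H x p, column-major), b1, vec(W2)
# (q x H), b2]. Inputs and outputs live on the [-1, 1] min-max scale; the
# et_model object stores the affine maps.

mlp_npar <- function(p, H, q) H * p + H + q * H + q

mlp_unpack <- function(theta, p, H, q) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(H * p)], H, p); i <- i + H * p
  b1 <- theta[i + seq_len(H)]; i <- i + H
  W2 <- matrix(theta[i + seq_len(q * H)], q, H); i <- i + q * H
  b2 <- theta[i + seq_len(q)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

transfer_fun <- function(name) {
  switch(name,
         tansig = list(f = tanh, fp = function(h) 1 - h^2),
         logsig = list(f = function(z) 1 / (1 + exp(-z)),
                       fp = function(h) h * (1 - h)),
         purelin = list(f = identity, fp = function(h) rep(1, length(h))),
         stop("unknown transfer function: ", name))
}

# Forward pass on scaled inputs X (N x p); returns scaled outputs (N x q)
# and the hidden activations.
mlp_forward_scaled <- function(theta, X, p, H, q, transfer) {
  w <- mlp_unpack(theta, p, H, q)
  tf <- transfer_fun(transfer)
  Z1 <- sweep(X %*% t(w$W1), 2, w$b1, `+`)
  Hh <- tf$f(Z1)
  Y <- sweep(Hh %*% t(w$W2), 2, w$b2, `+`)
  list(Y = Y, H = Hh)
}

# Residual vector (column-stacked over outputs) and its Jacobian w.r.t.
# theta, for the Gauss-Newton/Levenberg-Marquardt step.
mlp_residual_jacobian <- function(theta, X, T, p, H, q, transfer) {
  w <- mlp_unpack(theta, p, H, q)
  tf <- transfer_fun(transfer)
  N <- nrow(X)
  Z1 <- sweep(X %*% t(w$W1), 2, w$b1, `+`)
  Hh <- tf$f(Z1)
  Fp <- tf$fp(Hh)
  if (!is.matrix(Fp)) Fp <- matrix(Fp, N, H)
  Y <- sweep(Hh %*% t(w$W2), 2, w$b2, `+`)
  r <- as.vector(Y - T)
  Nw <- mlp_npar(p, H, q)
  J <- matrix(0, N * q, Nw)
  off_b1 <- H * p
  off_W2 <- H * p + H
  off_b2 <- H * p + H + q * H
  for (k in seq_len(q)) {
    rows <- (k - 1) * N + seq_len(N)
    for (j in seq_len(H)) {
      g <- w$W2[k, j] * Fp[, j]          # dY_k / dz1_j
      # W1[j, i] occupies column (i-1)*H + j
      J[rows, (seq_len(p) - 1) * H + j] <- g * X
      J[rows, off_b1 + j] <- g
      # W2[k, j] occupies column off_W2 + (j-1)*q + k
      J[rows, off_W2 + (j - 1) * q + k] <- Hh[, j]
    }
    J[rows, off_b2 + k] <- 1
  }
  list(r = r, J = J)
}

minmax_scaling <- function(x) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span)
}

apply_scaling <- function(x, sc) {
  sweep(sweep(x, 2, sc$lo, `-`), 2, sc$span, `/`) * 2 - 1
}

invert_scaling <- function(z, sc) {
  sweep(sweep((z + 1) / 2, 2, sc$span, `*`), 2, sc$lo, `+`)
}

# ---- Bayesian-regularised Levenberg-Marquardt ----------------------------

#' Training control parameters
#'
#' @param strategy `"bayesian_regularization"` (Levenberg-Marquardt on the
#'   regularised objective `F = beta E_D + alpha E_W` with MacKay evidence
#'   updates of `alpha` and `beta`) or `"gradient_descent_momentum"` (plain
#'   batch gradient descent, the only strategy that honours `learning_rate`
#'   and `momentum`).
#' @param max_epochs epoch budget (default 300).
#' @param ftol,ftol_epochs stop when the objective decreases by less than
#'   `ftol` for `ftol_epochs` consecutive epochs.
#' @param n_restarts random weight restarts per fit (default 5); the best
#'   model is kept and the across-restart dispersion reported.
#' @param learning_rate,momentum gradient-descent parameters (defaults 0.1
#'   and 0.4); ignored by the Bayesian-regularisation strategy, whose step
#'   length is set by the Levenberg-Marquardt damping.
#' @param mu0,mu_up,mu_down,mu_max Levenberg-Marquardt damping schedule.
#' @param init_range weights initialised uniformly in `[-init_range,
#'   init_range]`.
#' @param alpha0,beta0 initial regularisation and data-precision weights.
#' @param fixed_alpha set to a number (e.g. 0) to disable the evidence
#'   updates and train with a fixed weight penalty; 0 gives plain
#'   Levenberg-Marquardt least squares.
#' @return A list of class `et_control`.
#' @export
et_control <- function(strategy = c("bayesian_regularization",
                                    "gradient_descent_momentum"),
                       max_epochs = 300, ftol = 1e-9, ftol_epochs = 10,
                       n_restarts = 5, learning_rate = 0.1, momentum = 0.4,
                       mu0 = 1e-2, mu_up = 10, mu_down = 10, mu_max = 1e10,
                       init_range = 0.5, alpha0 = 0.01, beta0 = 1,
                       fixed_alpha = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(max_epochs >= 1, n_restarts >= 1, learning_rate > 0,
            momentum >= 0, mu0 > 0, init_range > 0)
  structure(list(strategy = strategy, max_epochs = max_epochs, ftol = ftol,
                 ftol_epochs = ftol_epochs, n_restarts = n_restarts,
                 learning_rate = learning_rate, momentum = momentum,
                 mu0 = mu0, mu_up = mu_up, mu_down = mu_down,
                 mu_max = mu_max, init_range = init_range, alpha0 = alpha0,
                 beta0 = beta0, fixed_alpha = fixed_alpha),
            class = "et_control")
}

br_train <- function(theta, X, T, p, H, q, transfer, control) {
  n <- length(T)
  Nw <- length(theta)
  fixed <- !is.null(control$fixed_alpha)
  alpha <- if (fixed) control$fixed_alpha else control$alpha0
  beta <- control$beta0
  rj <- mlp_residual_jacobian(theta, X, T, p, H, q, transfer)
  E_D <- 0.5 * sum(rj$r^2)
  E_W <- 0.5 * sum(theta^2)
  F_cur <- beta * E_D + alpha * E_W
  gamma_cur <- if (fixed) Nw else NA_real_
  mu <- control$mu0
  hist <- vector("list", control$max_epochs)
  flat <- 0L
  status <- "max_epochs"
  epoch <- 0L
  while (epoch < control$max_epochs) {
    epoch <- epoch + 1L
    g <- beta * crossprod(rj$J, rj$r) + alpha * theta
    A <- beta * crossprod(rj$J)
    diag(A) <- diag(A) + alpha
    F_before <- F_cur
    accepted <- FALSE
    while (mu <= control$mu_max) {
      M <- A
      diag(M) <- diag(M) + mu
      delta <- tryCatch(solve(M, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        theta_new <- theta + as.vector(delta)
        fw <- mlp_forward_scaled(theta_new, X, p, H, q, transfer)
        E_D_new <- 0.5 * sum((as.vector(fw$Y) - as.vector(T))^2)
        E_W_new <- 0.5 * sum(theta_new^2)
        F_new <- beta * E_D_new + alpha * E_W_new
        if (is.finite(F_new) && F_new <= F_cur) {
          theta <- theta_new
          E_D <- E_D_new; E_W <- E_W_new; F_cur <- F_new
          mu <- max(mu / control$mu_down, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * control$mu_up
    }
    if (!accepted) { status <- "damping_exhausted"; epoch <- epoch - 1L; break }
    rj <- mlp_residual_jacobian(theta, X, T, p, H, q, transfer)
    if (!fixed) {
      # MacKay evidence update of the hyperparameters
      Aacc <- beta * crossprod(rj$J)
      diag(Aacc) <- diag(Aacc) + alpha
      tr_inv <- tryCatch(sum(diag(solve(Aacc))), error = function(e) NA_real_)
      if (is.finite(tr_inv)) {
        gamma_cur <- min(max(Nw - 2 * alpha * tr_inv, 0), Nw)
        alpha <- min(max(gamma_cur / (2 * E_W + 1e-300), 1e-12), 1e12)
        beta <- min(max((n - gamma_cur) / (2 * E_D + 1e-300), 1e-12), 1e12)
        F_cur <- beta * E_D + alpha * E_W
      }  # near-singular Hessian: keep the previous hyperparameters
    }
    hist[[epoch]] <- data.frame(epoch = epoch, F = F_cur, E_D = E_D,
                                E_W = E_W, alpha = alpha, beta = beta,
                                gamma = gamma_cur, mu = mu,
                                F_drop = F_before - F_new)
    flat <- if (abs(F_before - F_new) < control$ftol) flat + 1L else 0L
    if (flat >= control$ftol_epochs) { status <- "converged"; break }
  }
  list(theta = theta, alpha = alpha, beta = beta, gamma = gamma_cur,
       E_D = E_D, E_W = E_W, F = F_cur, epochs = epoch, status = status,
       history = if (epoch > 0) do.call(rbind, hist[seq_len(epoch)]) else NULL)
}

gdm_train <- function(theta, X, T, p, H, q, transfer, control) {
  v <- numeric(length(theta))
  hist <- vector("list", control$max_epochs)
  for (epoch in seq_len(control$max_epochs)) {
    rj <- mlp_residual_jacobian(theta, X, T, p, H, q, transfer)
    g <- crossprod(rj$J, rj$r)
    v <- control$momentum * v - control$learning_rate * as.vector(g) / nrow(X)
    theta <- theta + v
    E_D <- 0.5 * sum(rj$r^2)
    hist[[epoch]] <- data.frame(epoch = epoch, F = E_D, E_D = E_D,
                                E_W = 0.5 * sum(theta^2), alpha = 0,
                                beta = 1, gamma = NA_real_, mu = NA_real_,
                                F_drop = NA_real_)
  }
  rj <- mlp_residual_jacobian(theta, X, T, p, H, q, transfer)
  E_D <- 0.5 * sum(rj$r^2)
  list(theta = theta, alpha = 0, beta = 1, gamma = NA_real_, E_D = E_D,
       E_W = 0.5 * sum(theta^2), F = E_D, epochs = control$max_epochs,
       status = "max_epochs", history = do.call(rbind, hist))
}

# ---- the user-facing fitting function ------------------------------------

#' Fit the electronic-tongue inverse model
#'
#' Trains a single-hidden-layer perceptron that maps the array potentials
#' (one column per electrode, mV) to the ion concentrations (mol/L). The
#' default architecture is 5 inputs, 8 hidden `tansig` units and 2 linear
#' outputs, trained by Bayesian regularisation: Levenberg-Marquardt descent
#' on \eqn{F = \beta E_D + \alpha E_W} with MacKay evidence updates
#' \eqn{\gamma = N_w - 2\alpha\,\mathrm{tr}(H^{-1})},
#' \eqn{\alpha \leftarrow \gamma/(2E_W)},
#' \eqn{\beta \leftarrow (n-\gamma)/(2E_D)} after each accepted step.
#' Inputs and outputs are min-max scaled to `[-1, 1]` on the training data.
#' Several seeded random restarts are run and the best model kept (by test
#' RMSE when a test set is supplied, otherwise by the final objective); the
#' across-restart dispersion estimates the model precision.
#'
#' @param x numeric matrix/data frame of potentials (samples x electrodes).
#' @param y numeric matrix/data frame of concentrations (samples x ions).
#' @param hidden hidden-layer size (default 8).
#' @param transfer hidden transfer function: `"tansig"` (default),
#'   `"logsig"` or `"purelin"`. The output layer is always linear.
#' @param x_test,y_test optional external test subset used for model
#'   selection across restarts and reported metrics.
#' @param control an [et_control()] list.
#' @param seed integer seed governing all weight initialisations.
#' @param log_outputs model log10 concentrations instead of linear ones
#'   (off by default).
#' @return An object of class `et_model`; see [predict.et_model()],
#'   [summary.et_model()], [plot.et_model()].
#' @export
et_fit <- function(x, y, hidden = 8,
                   transfer = c("tansig", "logsig", "purelin"),
                   x_test = NULL, y_test = NULL, control = et_control(),
                   seed = 1, log_outputs = FALSE) {
  transfer <- match.arg(transfer)
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 10)
  p <- ncol(x); q <- ncol(y); H <- hidden
  if (log_outputs && any(y <= 0))
    stop("log_outputs requires strictly positive concentrations; ",
         "designs with single-ion (zero-concentration) samples need the ",
         "default linear output scale")
  y_model <- if (log_outputs) log10(y) else y
  sc_x <- minmax_scaling(x)
  sc_y <- minmax_scaling(y_model)
  X <- apply_scaling(x, sc_x)
  T <- apply_scaling(y_model, sc_y)
  Nw <- mlp_npar(p, H, q)
  runs <- vector("list", control$n_restarts)
  crit <- numeric(control$n_restarts)
  rmse_tests <- rep(NA_real_, control$n_restarts)
  for (r in seq_len(control$n_restarts)) {
    theta0 <- with_seed(seed + (r - 1L),
                        stats::runif(Nw, -control$init_range, control$init_range))
    fit <- if (control$strategy == "bayesian_regularization")
      br_train(theta0, X, T, p, H, q, transfer, control)
    else gdm_train(theta0, X, T, p, H, q, transfer, control)
    runs[[r]] <- fit
    if (!is.null(x_test)) {
      pred <- predict_theta(fit$theta, as.matrix(x_test), p, H, q, transfer,
                            sc_x, sc_y, log_outputs)
      rmse_tests[r] <- sqrt(mean((pred - as.matrix(y_test))^2))
      crit[r] <- rmse_tests[r]
    } else {
      crit[r] <- fit$F
    }
  }
  best <- which.min(crit)
  fit <- runs[[best]]
  restarts <- data.frame(restart = seq_len(control$n_restarts),
                         F = vapply(runs, `[[`, numeric(1), "F"),
                         E_D = vapply(runs, `[[`, numeric(1), "E_D"),
                         epochs = vapply(runs, `[[`, numeric(1), "epochs"),
                         rmse_test = rmse_tests, criterion = crit)
  structure(list(theta = fit$theta, hidden = H, transfer = transfer,
                 n_inputs = p, n_outputs = q,
                 input_names = colnames(x), ions = colnames(y),
                 input_scaling = sc_x, output_scaling = sc_y,
                 log_outputs = log_outputs,
                 alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma,
                 E_D = fit$E_D, E_W = fit$E_W, F = fit$F,
                 epochs = fit$epochs, status = fit$status,
                 history = fit$history, restarts = restarts,
                 best_restart = best,
                 restart_sd = stats::sd(crit),
                 x = x, y = y, x_test = x_test, y_test = y_test,
                 seed = seed, control = control, call = match.call()),
            class = "et_model")
}

predict_theta <- function(theta, x, p, H, q, transfer, sc_x, sc_y,
                          log_outputs) {
  X <- apply_scaling(x, sc_x)
  Y <- mlp_forward_scaled(theta, X, p, H, q, transfer)$Y
  out <- invert_scaling(Y, sc_y)
  if (log_outputs) out <- 10^out
  out
}

#' Scan hidden-layer sizes and transfer functions
#'
#' Trains one model per candidate configuration (each with the configured
#' number of restarts, best kept) and tabulates test RMSE per ion and
#' pooled, together with the obtained-vs-expected comparison regression
#' (slope, intercept, correlation) per ion. The configuration minimising
#' the pooled test RMSE is marked as selected.
#'
#' @param x,y,x_test,y_test training and test data as in [et_fit()].
#' @param hidden_values candidate hidden-layer sizes (>= 2 values).
#' @param transfers candidate hidden transfer functions.
#' @param control an [et_control()] list.
#' @param seed integer master seed; each configuration derives its own.
#' @return Data frame of class `et_scan`, one row per configuration, with
#'   attribute `selected` (row index) and `models` (the fitted models).
#' @export
architecture_scan <- function(x, y, x_test, y_test,
                              hidden_values = c(2, 4, 6, 8, 10, 12),
                              transfers = "tansig", control = et_control(),
                              seed = 1) {
  grid <- expand.grid(hidden = hidden_values, transfer = transfers,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- data.frame(hidden = grid$hidden[i], transfer = grid$transfer[i])
    fit <- try(et_fit(x, y, hidden = grid$hidden[i],
                      transfer = grid$transfer[i], x_test = x_test,
                      y_test = y_test, control = control,
                      seed = seed + 1000L * i), silent = TRUE)
    if (inherits(fit, "try-error")) {
      row$error <- as.character(attr(fit, "condition")$message)
      rows[[i]] <- row
      next
    }
    models[[i]] <- fit
    pred <- predict(fit, newdata = as.matrix(x_test))
    yt <- as.matrix(y_test)
    row$rmse_pooled <- sqrt(mean((pred - yt)^2))
    for (k in seq_len(ncol(yt))) {
      nm <- colnames(yt)[k] %||% paste0("y", k)
      cr <- comparison_regression(pred[, k], yt[, k])
      row[[paste0("rmse_", nm)]] <- sqrt(mean((pred[, k] - yt[, k])^2))
      row[[paste0("slope_", nm)]] <- cr$slope
      row[[paste0("intercept_", nm)]] <- cr$intercept
      row[[paste0("r_", nm)]] <- cr$r
    }
    row$error <- NA_character_
    rows[[i]] <- row
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
  ok <- which(!is.na(out$rmse_pooled))
  attr(out, "selected") <- if (length(ok)) ok[which.min(out$rmse_pooled[ok])] else NA_integer_
  attr(out, "models") <- models
  class(out) <- c("et_scan", class(out))
  out
}
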