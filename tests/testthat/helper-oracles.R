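# Independent scalar oracles, written directly from the defining formulas
# and kept free of the package's own code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Davies activity coefficient, spelled out
oracle_gamma <- function(z, I, A = 0.511) {
  if (z == 0 || I == 0) return(1)
  10^(-A * z^2 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I))
}

# Ionic strength of a set of sodium-salt anions over a background
oracle_ionic_strength <- function(conc, charges, I_bg = 0) {
  I <- I_bg
  for (i in seq_along(conc)) {
    z <- charges[i]
    I <- I + 0.5 * (conc[i] * z^2 + conc[i] * abs(z) * 1^2)
  }
  unname(I)
}

# Full spreadsheet-style electrode potential: concentrations -> activities ->
# Nikolsky-Eisenmann, one interferent
oracle_potential <- function(e0, slope, c_i, z_i, a_bg, log_k = NULL,
                             c_j = 0, z_j = NULL, I_bg = 0) {
  conc <- c(c_i, c_j)
  charges <- c(z_i, if (is.null(z_j)) 0 else z_j)
  I <- oracle_ionic_strength(conc[conc > 0], charges[conc > 0], I_bg)
  a_i <- oracle_gamma(z_i, I) * c_i
  term <- 0
  if (!is.null(log_k) && c_j > 0)
    term <- 10^log_k * (oracle_gamma(z_j, I) * c_j)^(z_i / z_j)
  e0 + slope * log10(a_i + a_bg + term)
}

# Loop-based MLP forward pass (tansig/logsig/purelin hidden, linear output)
oracle_mlp_forward <- function(theta, X, p, H, q, transfer) {
  f <- switch(transfer, tansig = tanh,
              logsig = function(z) 1 / (1 + exp(-z)),
              purelin = identity)
  i <- 0
  W1 <- matrix(theta[i + seq_len(H * p)], H, p); i <- i + H * p
  b1 <- theta[i + seq_len(H)]; i <- i + H
  W2 <- matrix(theta[i + seq_len(q * H)], q, H); i <- i + q * H
  b2 <- theta[i + seq_len(q)]
  Y <- matrix(0, nrow(X), q)
  for (n in seq_len(nrow(X))) {
    h <- numeric(H)
    for (j in seq_len(H)) h[j] <- f(sum(W1[j, ] * X[n, ]) + b1[j])
    for (k in seq_len(q)) Y[n, k] <- sum(W2[k, ] * h) + b2[k]
  }
  Y
}

# Assemble a bare et_model for forward-pass tests
make_raw_model <- function(theta, p, H, q, sc_x, sc_y, transfer = "tansig",
                           ions = paste0("y", seq_len(q))) {
  structure(list(theta = theta, hidden = H, transfer = transfer,
                 n_inputs = p, n_outputs = q, ions = ions,
                 input_scaling = sc_x, output_scaling = sc_y,
                 log_outputs = FALSE),
            class = "et_model")
}

quiet_panel <- function() default_panel(noise_sd = 0, drift_sd = 0)

act_bg <- function(I = 0.05) activity_params(background_ionic_strength = I)
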