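# The discrete-time hazard network: one hidden layer of logistic-sigmoid
# nodes and K logistic-sigmoid output nodes, one conditional hazard per time
# interval. Training minimizes the masked cross-entropy of the discrete-time
# likelihood expansion plus a weight-decay penalty on the weights (not the
# biases), by full-batch resilient back-propagation. Training is
# deterministic given the seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Resilient back-propagation settings
#'
#' @param eta_plus,eta_minus Step-size multipliers on gradient-sign agreement
#'   / disagreement (defaults 1.2 and 0.5).
#' @param delta0 Initial per-weight step (default 0.01).
#' @param delta_min,delta_max Step bounds (defaults 1e-6 and 50).
#' @param epochs Maximum number of full-batch epochs (default 400).
#' @param patience Stop after this many epochs without relative improvement
#'   better than `tol` of the best loss (default 40).
#' @param tol Relative improvement threshold for the plateau rule
#'   (default 1e-6).
#' @return A list of rprop parameters.
#' @export
rprop_control <- function(eta_plus = 1.2, eta_minus = 0.5, delta0 = 0.01,
                          delta_min = 1e-6, delta_max = 50,
                          epochs = 400, patience = 40, tol = 1e-6) {
  list(
    eta_plus = eta_plus, eta_minus = eta_minus, delta0 = delta0,
    delta_min = delta_min, delta_max = delta_max,
    epochs = epochs, patience = patience, tol = tol
  )
}

init_weights <- function(p, H, K, seed, event_rate = NULL) {
  with_seed(seed, {
    W1 <- matrix(runif(p * H, -0.5, 0.5) / sqrt(p + 1), p, H)
    b1 <- runif(H, -0.1, 0.1)
    W2 <- matrix(runif(H * K, -0.5, 0.5) / sqrt(H + 1), H, K)
    # starting the output biases at the pooled per-interval hazard's logit
    # puts the network at the covariate-free model
    b2 <- if (is.null(event_rate)) {
      rep(qlogis(0.05), K)
    } else {
      qlogis(pmin(pmax(event_rate, 1e-4), 1 - 1e-4))
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  })
}

net_forward <- function(w, x) {
  z <- sigmoid(sweep(x %*% w$W1, 2, w$b1, "+"))
  h <- sigmoid(sweep(z %*% w$W2, 2, w$b2, "+"))
  list(z = z, h = h)
}

# Masked cross-entropy + weight decay, and its exact gradient.
net_loss_grad <- function(w, x, at_risk, event, decay, grad = TRUE) {
  fwd <- net_forward(w, x)
  h <- pmin(pmax(fwd$h, 1e-12), 1 - 1e-12)
  ce <- -sum(at_risk * (event * log(h) + (1 - event) * log(1 - h)))
  loss <- ce + decay * (sum(w$W1^2) + sum(w$W2^2))
  if (!grad) {
    return(list(loss = loss))
  }
  g2 <- at_risk * (fwd$h - event) # sigmoid + cross-entropy shortcut
  gW2 <- crossprod(fwd$z, g2) + 2 * decay * w$W2
  gb2 <- colSums(g2)
  g1 <- (g2 %*% t(w$W2)) * fwd$z * (1 - fwd$z)
  gW1 <- crossprod(x, g1) + 2 * decay * w$W1
  gb1 <- colSums(g1)
  list(loss = loss, grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

flatten_w <- function(w) c(w$W1, w$b1, w$W2, w$b2)

unflatten_w <- function(v, p, H, K) {
  i <- 0
  take <- function(n) {
    out <- v[(i + 1):(i + n)]
    i <<- i + n
    out
  }
  list(
    W1 = matrix(take(p * H), p, H), b1 = take(H),
    W2 = matrix(take(H * K), H, K), b2 = take(K)
  )
}

#' Train a discrete-time hazard network
#'
#' Fits the single-hidden-layer hazard network on a standardized design
#' matrix and discrete-time targets (see [make_targets()]), minimizing the
#' masked cross-entropy plus `decay * sum(weights^2)` by full-batch resilient
#' back-propagation (step-size adaptation on gradient sign changes). The best
#' weights seen are returned, so the reported accepted-loss trajectory is
#' nonincreasing.
#'
#' @param x Numeric n x p design matrix (standardized columns).
#' @param targets Output of [make_targets()] for the same records.
#' @param hidden Number of hidden nodes H (default 18).
#' @param decay Weight-decay coefficient on W1/W2 (biases unpenalized).
#' @param control A [rprop_control()] list.
#' @param seed Integer seed for the small-uniform weight initialization.
#' @return An `ihtsa_network` object: weights, dimensions, the time grid,
#'   `loss_trace` (per epoch) and `accepted_loss` (best-so-far sequence).
#' @export
train_network <- function(x, targets, hidden = 18, decay = 1e-4,
                          control = rprop_control(), seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  K <- targets$grid$K
  if (sum(targets$event) == 0) {
    abort("no events in the training data", class = "ihtsa_training_error")
  }
  pooled <- colSums(targets$event) / pmax(colSums(targets$at_risk), 1)
  w <- init_weights(p, hidden, K, seed, event_rate = pooled)
  v <- flatten_w(w)
  nv <- length(v)
  delta <- rep(control$delta0, nv)
  g_prev <- rep(0, nv)
  # decay applies to W1/W2 entries only
  lg <- net_loss_grad(w, x, targets$at_risk, targets$event, decay)
  if (!is.finite(lg$loss)) {
    abort("non-finite loss at initialization", class = "ihtsa_training_error")
  }
  best_v <- v
  best_loss <- lg$loss
  loss_trace <- numeric(control$epochs)
  accepted <- lg$loss
  stall <- 0
  epoch <- 0
  while (epoch < control$epochs) {
    epoch <- epoch + 1
    g <- flatten_w(lg$grad)
    sign_prod <- g * g_prev
    delta <- ifelse(sign_prod > 0, pmin(delta * control$eta_plus, control$delta_max),
      ifelse(sign_prod < 0, pmax(delta * control$eta_minus, control$delta_min), delta)
    )
    g_eff <- ifelse(sign_prod < 0, 0, g) # iRprop-: forget sign-flipped gradients
    v <- v - sign(g_eff) * delta
    g_prev <- g_eff
    w <- unflatten_w(v, p, hidden, K)
    lg <- net_loss_grad(w, x, targets$at_risk, targets$event, decay)
    if (!is.finite(lg$loss)) {
      abort(paste0("non-finite training loss at epoch ", epoch),
        class = "ihtsa_training_error"
      )
    }
    loss_trace[epoch] <- lg$loss
    if (lg$loss < best_loss * (1 - control$tol)) {
      stall <- 0
    } else {
      stall <- stall + 1
    }
    if (lg$loss < best_loss) {
      best_loss <- lg$loss
      best_v <- v
      accepted <- c(accepted, lg$loss)
    }
    if (stall >= control$patience) break
  }
  w <- unflatten_w(best_v, p, hidden, K)
  structure(
    list(
      W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
      input_dim = p, hidden = hidden, K = K,
      grid = targets$grid,
      training_meta = list(
        decay = decay, epochs_run = epoch, seed = seed,
        final_loss = best_loss
      ),
      loss_trace = loss_trace[seq_len(epoch)],
      accepted_loss = accepted
    ),
    class = "ihtsa_network"
  )
}

#' Per-interval hazards predicted by one network
#'
#' @param network An `ihtsa_network`.
#' @param x Design matrix with the network's input columns.
#' @return n x K matrix of conditional hazards in (0, 1).
#' @export
predict_hazard <- function(network, x) {
  x <- as.matrix(x)
  if (ncol(x) != network$input_dim) {
    abort("design matrix width does not match network input dimension",
      class = "ihtsa_prediction_error"
    )
  }
  net_forward(network, x)$h
}

#' @export
print.ihtsa_network <- function(x, ...) {
  cat(
    "<ihtsa_network> ", x$input_dim, " inputs, ", x$hidden,
    " hidden nodes, ", x$K, " time intervals\n",
    sep = ""
  )
  invisible(x)
}
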