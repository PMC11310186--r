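#' Initialise the two-layer mean-pooling encoder
#'
#' The encoder maps node features through two mean-pooling (MP) graph
#' layers, `MP(H, A) = ReLU(D^-1 (A + I) H Theta)`, each producing
#' `hidden_dim`-dimensional representations (default 16), followed by a
#' linear + sigmoid classification head for binary node classification.
#' Parameters use seeded uniform Glorot initialisation (limit
#' `sqrt(6 / (fan_in + fan_out))`), the standard choice for ReLU graph
#' layers.
#'
#' @param n_features input feature dimension F.
#' @param hidden_dim embedding dimension F' of both MP layers (default 16).
#' @param seed integer seed for the initialisation stream.
#' @return an object of class `encoder_model` with `theta1` (F x F'),
#'   `theta2` (F' x F'), `head_w` (F'), `head_b` (scalar).
#' @export
encoder_model <- function(n_features, hidden_dim = 16L, seed = 1L) {
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  with_local_seed(seed, {
    structure(
      list(
        theta1 = glorot(n_features, hidden_dim),
        theta2 = glorot(hidden_dim, hidden_dim),
        head_w = as.numeric(glorot(hidden_dim, 1L)),
        head_b = 0,
        hidden_dim = as.integer(hidden_dim),
        init_seed = as.integer(seed)
      ),
      class = "encoder_model"
    )
  })
}

# Row-stochastic propagation operator P = D^-1 (A + I): self-loops get
# weight 1 (clique weights never apply to them); row i of P is a convex
# combination over i's closed neighbourhood, with clique weights acting as
# aggregation weights.
propagation_operator <- function(adjacency) {
  n <- nrow(adjacency)
  a_hat <- adjacency + Matrix::Diagonal(n)
  d_hat <- Matrix::rowSums(a_hat)
  Matrix::Diagonal(n, 1 / d_hat) %*% a_hat
}

#' One mean-pooling graph layer
#'
#' Computes `ReLU(D^-1 (A + I) H Theta)`: a degree-normalised weighted mean
#' over each node's closed neighbourhood followed by a learned linear map
#' and rectification. Self-loops (weight 1) are added internally.
#'
#' @param h node-feature matrix (N x d).
#' @param adjacency non-negative weighted adjacency (N x N, zero diagonal).
#' @param theta transformation matrix (d x d').
#' @return N x d' matrix.
#' @export
mean_pool_layer <- function(h, adjacency, theta) {
  h <- as.matrix(h)
  if (ncol(h) != nrow(theta))
    stop(sprintf("dimension mismatch: features have %d columns, theta has %d rows",
                 ncol(h), nrow(theta)), call. = FALSE)
  p <- propagation_operator(adjacency)
  z <- as.matrix(p %*% h) %*% theta
  pmax(z, 0)
}

#' Encode all nodes with the two-layer mean-pooling encoder
#'
#' `E(X, A) = MP2(MP1(X, A), A)`; both layers share the graph and produce
#' `hidden_dim`-dimensional embeddings.
#'
#' @param x node features (N x F matrix or `encounter_matrix`).
#' @param adjacency weighted adjacency or a `patient_graph`.
#' @param model an [encoder_model()].
#' @return N x F' embedding matrix.
#' @export
encode <- function(x, adjacency, model) {
  if (inherits(x, "encounter_matrix")) x <- x$features
  if (inherits(adjacency, "patient_graph")) adjacency <- adjacency$adjacency
  h1 <- mean_pool_layer(x, adjacency, model$theta1)
  mean_pool_layer(h1, adjacency, model$theta2)
}

#' Predict outcome scores from embeddings
#'
#' Linear head + sigmoid; scores are clamped to `[eps, 1 - eps]`
#' (`eps = 1e-7`) so the cross-entropy loss never sees exact 0 or 1.
#'
#' @param embeddings N x F' matrix.
#' @param model an [encoder_model()].
#' @param eps clamping constant.
#' @return list with `scores` (length-N vector strictly inside (0, 1)) and
#'   `embeddings`, class `prediction`.
#' @export
predict_scores <- function(embeddings, model, eps = 1e-7) {
  z <- as.numeric(embeddings %*% model$head_w + model$head_b)
  s <- stats::plogis(z)
  s <- pmin(pmax(s, eps), 1 - eps)
  structure(list(scores = s, embeddings = embeddings), class = "prediction")
}

#' Binary cross-entropy loss
#'
#' `-(1/N) sum(y log s + (1 - y) log(1 - s))` with `y` the 0/1 ground truth
#' and `s` the predicted score.
#'
#' @param scores predicted scores in (0, 1).
#' @param labels 0/1 vector of the same length.
#' @return non-negative scalar.
#' @export
bce_loss <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  -mean(labels * log(scores) + (1 - labels) * log(1 - scores))
}

# Full forward + backward pass. `p` is the (sparse) propagation operator for
# the current epoch's graph; the loss is the mean BCE over `idx` (the
# mini-batch nodes) while message passing always uses the whole graph.
# Returns the loss and analytic gradients for all parameters.
model_gradients <- function(p, x, labels, idx, model, eps = 1e-7) {
  px <- as.matrix(p %*% x)
  z1 <- px %*% model$theta1
  h1 <- pmax(z1, 0)
  ph1 <- as.matrix(p %*% h1)
  z2 <- ph1 %*% model$theta2
  h2 <- pmax(z2, 0)
  zs <- as.numeric(h2 %*% model$head_w + model$head_b)
  s <- stats::plogis(zs)
  s_clamped <- pmin(pmax(s, eps), 1 - eps)
  loss <- bce_loss(s_clamped[idx], labels[idx])

  b <- length(idx)
  dz <- numeric(length(s))
  dz[idx] <- (s[idx] - labels[idx]) / b # d loss / d head pre-activation

  g_head_w <- as.numeric(crossprod(h2, dz))
  g_head_b <- sum(dz)

  dh2 <- outer(dz, model$head_w)
  dz2 <- dh2 * (z2 > 0)
  g_theta2 <- crossprod(ph1, dz2)

  dh1 <- as.matrix(Matrix::crossprod(p, dz2)) %*% t(model$theta2)
  dz1 <- dh1 * (z1 > 0)
  g_theta1 <- crossprod(px, dz1)

  list(
    loss = loss, scores = s_clamped,
    grads = list(theta1 = g_theta1, theta2 = g_theta2,
                 head_w = g_head_w, head_b = g_head_b)
  )
}

# Adam optimiser state and update (standard decay constants, no weight
# decay).
adam_state <- function(model) {
  zeros <- function(par) if (is.matrix(par)) par * 0 else par * 0
  list(
    m = list(theta1 = zeros(model$theta1), theta2 = zeros(model$theta2),
             head_w = zeros(model$head_w), head_b = 0),
    v = list(theta1 = zeros(model$theta1), theta2 = zeros(model$theta2),
             head_w = zeros(model$head_w), head_b = 0),
    t = 0L
  )
}

adam_step <- function(model, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in c("theta1", "theta2", "head_w", "head_b")) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    m_hat <- state$m[[nm]] / (1 - beta1^state$t)
    v_hat <- state$v[[nm]] / (1 - beta2^state$t)
    model[[nm]] <- model[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
  }
  list(model = model, state = state)
}
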