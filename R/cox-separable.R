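# Separable L1-penalized Cox engine.
#
# The multivariate objective used here is separable across genes: for gene j
# with coefficient b,
#
#   l_j(b) = sum_k [ x_kj b - log sum_{m in R_k} exp(x_mj b) ] - lambda |b|
#
# summed over event times t_k with risk sets R_k.  Each gene therefore has
# its own one-dimensional concave problem, which we solve for all genes
# simultaneously by a safeguarded Newton iteration on the penalized score.
# Ties are handled by the Efron approximation.  Risk-set sums are computed
# as crossproducts with precomputed 0/1 risk-set indicator matrices, which
# keeps a full penalty-path fit cheap even inside nested cross-validation.

cox_sep_prepare <- function(x, time, event) {
  stopifnot(nrow(x) == length(time), length(time) == length(event))
  event <- as.integer(event)
  if (sum(event) < 1L) stop_input("no events in survival data")
  et <- sort(unique(time[event == 1L]))          # distinct event times
  n <- length(time)
  risk <- outer(time, et, `>=`) * 1              # n x E risk-set indicator
  died <- outer(time, et, `==`) * event          # n x E tied-event indicator
  d <- colSums(died)                             # events per event time
  env <- new.env(parent = emptyenv())            # memo for the zero score
  list(x = x, event = event, n_event = sum(event),
       risk = risk, died = died, d = d, memo = env)
}

# Log partial likelihood only (cheap path for cross-validation criteria).
cox_sep_loglik <- function(prep, beta) {
  x <- prep$x
  n <- nrow(x)
  eta <- x * rep(beta, each = n)
  w <- exp(eta)
  S <- crossprod(prep$risk, w)                   # E x p risk-set sums
  D <- crossprod(prep$died, w)
  ll <- colSums(eta * prep$event)
  maxd <- max(prep$d)
  for (l in 0:(maxd - 1L)) {
    g <- which(prep$d > l)
    frac <- l / prep$d[g]
    ll <- ll - colSums(log(S[g, , drop = FALSE] - frac * D[g, , drop = FALSE]))
  }
  unname(ll)
}

# Log partial likelihood, score and information for every gene at its own
# coefficient, Efron tie correction.  beta holds one value per column of x.
cox_sep_score <- function(prep, beta) {
  x <- prep$x
  n <- nrow(x); p <- ncol(x)
  eta <- x * rep(beta, each = n)
  w <- exp(eta)
  wx <- w * x
  wxx <- wx * x
  S <- crossprod(prep$risk, w)
  Sx <- crossprod(prep$risk, wx)
  Sxx <- crossprod(prep$risk, wxx)
  D <- crossprod(prep$died, w)
  Dx <- crossprod(prep$died, wx)
  Dxx <- crossprod(prep$died, wxx)

  loglik <- colSums(eta * prep$event)
  grad <- colSums(x * prep$event)
  info <- numeric(p)
  maxd <- max(prep$d)
  for (l in 0:(maxd - 1L)) {
    g <- which(prep$d > l)
    frac <- l / prep$d[g]
    den <- S[g, , drop = FALSE] - frac * D[g, , drop = FALSE]
    num1 <- Sx[g, , drop = FALSE] - frac * Dx[g, , drop = FALSE]
    num2 <- Sxx[g, , drop = FALSE] - frac * Dxx[g, , drop = FALSE]
    loglik <- loglik - colSums(log(den))
    grad <- grad - colSums(num1 / den)
    info <- info + colSums(num2 / den - (num1 / den)^2)
  }
  list(loglik = unname(loglik), grad = unname(grad), info = unname(info))
}

# Score at beta = 0, memoized per prepared dataset (shared by every lambda
# on a penalty path).
cox_sep_score0 <- function(prep) {
  if (is.null(prep$memo$sc0))
    prep$memo$sc0 <- cox_sep_score(prep, numeric(ncol(prep$x)))
  prep$memo$sc0
}

# L1-penalized per-gene maximizer.  A gene stays at zero iff |U_j(0)| <=
# lambda (soft-threshold condition); otherwise Newton on U_j(b) =
# lambda * sign(U_j(0)), clipped so the iterate never crosses zero.
cox_sep_fit <- function(prep, lambda, beta_init = NULL, tol = 1e-9,
                        max_iter = 50L) {
  p <- ncol(prep$x)
  sc0 <- cox_sep_score0(prep)
  sgn <- sign(sc0$grad)
  active <- abs(sc0$grad) > lambda + 1e-12
  beta <- numeric(p)
  if (!any(active)) return(list(beta = beta, active = active))
  b <- if (is.null(beta_init)) numeric(p) else beta_init
  b[!active] <- 0
  b[active & (sign(b) != sgn)] <- 0     # warm start must match the sign
  for (it in seq_len(max_iter)) {
    sc <- cox_sep_score(prep, b)
    g_pen <- sc$grad - lambda * sgn
    conv <- !active | abs(g_pen) < tol
    if (all(conv)) break
    step <- g_pen / pmax(sc$info, 1e-10)
    step[!active] <- 0
    step[abs(step) > 2] <- 2 * sign(step[abs(step) > 2])   # safeguard
    b_new <- b + step
    crossed <- active & (sgn * b_new < 0)
    b_new[crossed] <- sgn[crossed] * 1e-12
    b <- ifelse(conv, b, b_new)
  }
  beta[active] <- b[active]
  list(beta = beta, active = active)
}

# Largest useful penalty: max_j |U_j(0)|, above which every gene is zero.
cox_sep_lambda_max <- function(prep) {
  max(abs(cox_sep_score0(prep)$grad))
}
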