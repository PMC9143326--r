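# Independent dynamic-programming oracles on small finite MDPs, plus a bridge
# that turns an enumerated MDP into the package's transition-sample format.
# These never call the package's FQI/FQE code paths.

# random finite MDP with transition probabilities in eighths, so that a sample
# set with exact empirical frequencies can be enumerated
make_toy_mdp <- function(n_states, n_actions, seed) {
  set.seed(seed)
  P <- array(0, c(n_states, n_actions, n_states))
  for (s in seq_len(n_states)) {
    for (a in seq_len(n_actions)) {
      counts <- as.numeric(stats::rmultinom(1, 8, rep(1, n_states)))
      P[s, a, ] <- counts / 8
    }
  }
  R <- matrix(round(stats::runif(n_states * n_actions, -1, 0), 3),
              n_states, n_actions)
  list(n_states = n_states, n_actions = n_actions, P = P, R = R)
}

# deterministic variant (point-mass transitions)
make_toy_mdp_det <- function(n_states, n_actions, seed) {
  m <- make_toy_mdp(n_states, n_actions, seed)
  for (s in seq_len(m$n_states)) {
    for (a in seq_len(m$n_actions)) {
      nxt <- which.max(m$P[s, a, ])
      m$P[s, a, ] <- 0
      m$P[s, a, nxt] <- 1
    }
  }
  m
}

value_iteration <- function(mdp, gamma, tol = 1e-14, max_iter = 5000L) {
  Q <- matrix(0, mdp$n_states, mdp$n_actions)
  for (k in seq_len(max_iter)) {
    V <- apply(Q, 1L, max)
    Qn <- mdp$R + gamma * apply(mdp$P, c(1, 2), function(p) sum(p * V))
    if (max(abs(Qn - Q)) < tol) { Q <- Qn; break }
    Q <- Qn
  }
  list(Q = Q, V = apply(Q, 1L, max),
       policy = apply(Q, 1L, which.max))
}

# exact evaluation of a fixed deterministic policy by linear solve
exact_policy_eval <- function(mdp, policy, gamma) {
  S <- mdp$n_states
  Ppi <- t(vapply(seq_len(S), function(s) mdp$P[s, policy[s], ],
                  numeric(S)))
  rpi <- vapply(seq_len(S), function(s) mdp$R[s, policy[s]], numeric(1))
  V <- solve(diag(S) - gamma * Ppi, rpi)
  Q <- mdp$R + gamma * apply(mdp$P, c(1, 2), function(p) sum(p * V))
  list(V = V, Q = Q)
}

# one-hot state encoding for state s
toy_state_names <- function(n_states) paste0("s_", seq_len(n_states))

toy_onehot <- function(s, n_states) {
  m <- matrix(0, length(s), n_states,
              dimnames = list(NULL, toy_state_names(n_states)))
  m[cbind(seq_along(s), s)] <- 1
  m
}

# minimal catalog/spec shims so toy samples flow through fqi()/fqe()
toy_catalog <- function(n_actions) {
  data.frame(index = seq_len(n_actions),
             route = c("NONE", rep("IV", n_actions - 1L)),
             po_level = 0L,
             iv_level = c(0L, seq_len(n_actions - 1L)),
             label = c("NONE", paste0("A", seq_len(n_actions - 1L))))
}

# enumerate a sample set whose empirical transition frequencies EQUAL the MDP's
# transition law (8 samples per state-action pair, times `reps`)
toy_samples <- function(mdp, gamma, reps = 2L) {
  s_l <- integer(0); a_l <- integer(0); sp_l <- integer(0)
  for (s in seq_len(mdp$n_states)) {
    for (a in seq_len(mdp$n_actions)) {
      counts <- round(mdp$P[s, a, ] * 8)
      nxt <- rep(seq_len(mdp$n_states), counts)
      s_l <- c(s_l, rep(s, length(nxt)))
      a_l <- c(a_l, rep(a, length(nxt)))
      sp_l <- c(sp_l, nxt)
    }
  }
  s_l <- rep(s_l, reps); a_l <- rep(a_l, reps); sp_l <- rep(sp_l, reps)
  n <- length(s_l)
  spec <- list(electrolyte = "K", gamma = gamma,
               catalog = toy_catalog(mdp$n_actions),
               reference_range = c(0, 1), reward_form = "indicator",
               state_features = toy_state_names(mdp$n_states))
  structure(list(
    state = toy_onehot(s_l, mdp$n_states),
    next_state = toy_onehot(sp_l, mdp$n_states),
    action = a_l,
    next_action = rep(NA_integer_, n),
    reward = mdp$R[cbind(s_l, a_l)],
    phi = matrix(0, n, 4, dimnames = list(NULL, c("iv", "po", "high", "low"))),
    terminal = rep(FALSE, n),
    visit_id = sprintf("T%05d", seq_len(n)),
    bin = rep(0L, n),
    spec = spec
  ), class = "transition_set")
}

# Q matrix of a fitted object over all toy states/actions
toy_q_matrix <- function(fit, mdp) {
  S <- toy_onehot(seq_len(mdp$n_states), mdp$n_states)
  predict(fit, S)
}

# a policy object from an explicit action vector (state id -> action)
toy_policy <- function(action_by_state, n_states) {
  function(states) {
    s <- max.col(states[, toy_state_names(n_states), drop = FALSE],
                 ties.method = "first")
    action_by_state[s]
  }
}
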