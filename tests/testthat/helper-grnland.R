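# shared fixtures and independent oracles, built in code

sigmoid <- function(x, a = 1, b = 0) 1 / (1 + exp(-a * (x - b)))

# two-gene chain: gene 1 (input) activates gene 2
chain2 <- function() grn(matrix(c(0L, 1L, 0L, 0L), 2, 2), output = 2L)

# three-gene chain: 1 -> 2 -> 3, output gene 3
chain3 <- function() {
  J <- matrix(0L, 3, 3)
  J[2, 1] <- 1L
  J[3, 2] <- 1L
  grn(J, output = 3L)
}

# closed-form fitness of the two-gene chain: x2*(I) = R(R(I)), f = s_2
chain2_fitness_oracle <- function() {
  x2 <- function(I) sigmoid(sigmoid(I))
  abs(x2(1) - x2(0))
}

# independent steady state by plain R iteration (no package dynamics code)
iterate_oracle <- function(J, I, x, a = 1, b = 0, steps = 200) {
  for (t in seq_len(steps)) {
    h <- as.numeric(J %*% x)
    h[1] <- h[1] + I
    x <- sigmoid(h, a, b)
  }
  x
}

# independent motif census: per gene triple, classify the induced subgraph
motif_oracle <- function(net) {
  J <- net$J
  n <- nrow(J)
  counts <- c(pos_fbl = 0L, neg_fbl = 0L, pos_ffl = 0L, neg_ffl = 0L)
  if (n < 3) return(counts)
  for (trip in utils::combn(n, 3, simplify = FALSE)) {
    S <- J[trip, trip]
    if (sum(S != 0) != 3) next
    # a triangle covers all three unordered pairs
    covered <- all((S != 0 | t(S) != 0)[upper.tri(S)])
    if (!covered) next
    is_cycle <- all(rowSums(S != 0) == 1) && all(colSums(S != 0) == 1)
    positive <- prod(S[S != 0]) > 0
    cls <- if (is_cycle) {
      if (positive) "pos_fbl" else "neg_fbl"
    } else {
      if (positive) "pos_ffl" else "neg_ffl"
    }
    counts[cls] <- counts[cls] + 1L
  }
  counts
}

# wrap a density of states as a weight table usable by entropic_sample();
# used to run the measurement stage under exact weights
weights_from_density <- function(density, state_net, params = dyn_params(),
                                 control = wl_control()) {
  structure(list(log_weight = -density$table$log_states,
                 log_states = density$table$log_states,
                 visit_histogram = density$table$count,
                 visited = !is.na(density$table$log_states),
                 converged = TRUE, final_mod_factor = 0,
                 n_proposals = 0, n_stages = 0L, accept_rate = NA_real_,
                 state = state_net$J, state_f = NA_real_,
                 state_output = NA_integer_,
                 bins = density$bins,
                 n_genes = state_net$n_genes, n_edges = state_net$n_edges,
                 params = params, control = control),
            class = "wl_weights")
}

# first structurally valid random network at the given size
random_valid_net <- function(n_genes, n_edges, params = dyn_params()) {
  repeat {
    net <- random_grn(n_genes, n_edges)
    fit <- evaluate_fitness(net, params)
    if (fit$valid) {
      net$output <- fit$output
      attr(net, "f") <- fit$f
      return(net)
    }
  }
}
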