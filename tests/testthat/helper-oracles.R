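# Independent oracles and small constructors used across the suite.

# Build a bare causal_graph structure for graph-theory tests, bypassing the
# Key-Event validation (random DAGs have no outcome semantics).
toy_graph <- function(edges, nodes) {
  edges <- if (is.null(edges) || nrow(edges) == 0) {
    tibble::tibble(source = character(), target = character(),
                   sign = character(), mechanism = character(),
                   relationship_number = integer(), feedback = logical())
  } else {
    tibble::tibble(source = edges[, 1], target = edges[, 2],
                   sign = "activates", mechanism = "other",
                   relationship_number = NA_integer_, feedback = FALSE)
  }
  structure(list(
    nodes = tibble::tibble(
      id = nodes, label = nodes, kind = "process", measurable = FALSE,
      genes = replicate(length(nodes), character(0), simplify = FALSE),
      sufficient = FALSE, expected_direction = "none"),
    edges = edges,
    outcome_id = nodes[length(nodes)]), class = "causal_graph")
}

# Brute-force d-separation oracle: enumerate every simple undirected path
# between a and b and apply the per-path blocking rules (observed chain or
# fork node blocks; a collider blocks unless it or a descendant is
# observed). Nodes are integer indices 1..n; edges an m x 2 index matrix.
dsep_path_oracle <- function(n, edges, a, b, given) {
  children <- lapply(seq_len(n), function(v) edges[edges[, 1] == v, 2])
  neighbors <- lapply(seq_len(n), function(v)
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])))
  desc <- function(v) {
    seen <- logical(n); stack <- children[[v]]
    while (length(stack)) {
      w <- stack[[1]]; stack <- stack[-1]
      if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, children[[w]]) }
    }
    which(seen)
  }
  has_edge <- function(x, y) any(edges[, 1] == x & edges[, 2] == y)
  path_open <- function(path) {
    if (length(path) == 2) return(TRUE)
    for (k in 2:(length(path) - 1)) {
      v <- path[k]
      into_prev <- has_edge(path[k - 1], v)   # prev -> v
      into_next <- has_edge(path[k + 1], v)   # next -> v
      collider <- into_prev && into_next
      if (collider) {
        if (!(v %in% given) && !any(desc(v) %in% given)) return(FALSE)
      } else {
        if (v %in% given) return(FALSE)
      }
    }
    TRUE
  }
  found_open <- FALSE
  walk <- function(path) {
    if (found_open) return()
    v <- path[length(path)]
    if (v == b) {
      if (path_open(path)) found_open <<- TRUE
      return()
    }
    for (w in neighbors[[v]]) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(a)
  !found_open
}

# All labelled DAGs on n nodes: orient each unordered pair as absent,
# forward or backward, keep the acyclic ones. Returns a list of edge
# matrices.
enumerate_dags <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  out <- list()
  for (code in 0:(3^m - 1)) {
    digits <- (code %/% 3^(seq_len(m) - 1)) %% 3
    src <- c(pairs[digits == 1, 1], pairs[digits == 2, 2])
    dst <- c(pairs[digits == 1, 2], pairs[digits == 2, 1])
    ed <- cbind(src, dst)
    # Kahn acyclicity check
    indeg <- tabulate(ed[, 2], n)
    queue <- which(indeg == 0); removed <- 0
    ed2 <- ed
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; removed <- removed + 1
      outs <- which(ed2[, 1] == v)
      for (w in ed2[outs, 2]) {
        indeg[w] <- indeg[w] - 1
        if (indeg[w] == 0) queue <- c(queue, w)
      }
      if (length(outs)) ed2 <- ed2[-outs, , drop = FALSE]
    }
    if (removed == n) out[[length(out) + 1]] <- ed
  }
  out
}

# Random DAG: edges oriented along a random permutation.
random_dag <- function(n, p = 0.4) {
  ord <- sample(n)
  pairs <- t(utils::combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  ed <- pairs[keep, , drop = FALSE]
  flip <- match(ed[, 1], ord) > match(ed[, 2], ord)
  ed[flip, ] <- ed[flip, 2:1]
  ed
}

# Compare d_separated() with the path oracle over every query on a DAG.
check_dsep_against_oracle <- function(edges, n) {
  nodes <- paste0("n", seq_len(n))
  g <- toy_graph(if (nrow(edges)) cbind(nodes[edges[, 1]], nodes[edges[, 2]])
                 else NULL, nodes)
  pairs <- t(utils::combn(n, 2))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    rest <- setdiff(seq_len(n), c(a, b))
    subsets <- if (length(rest)) {
      # index-based combn: combn(x, k) on a length-1 x would expand 1:x
      unlist(lapply(0:length(rest), function(k)
        lapply(utils::combn(length(rest), k, simplify = FALSE),
               function(i) rest[i])), recursive = FALSE)
    } else list(integer(0))
    for (S in subsets) {
      got <- d_separated(g, nodes[a], nodes[b], nodes[S])
      want <- dsep_path_oracle(n, edges, a, b, S)
      if (!identical(got, want)) {
        return(list(ok = FALSE, edges = edges, a = a, b = b, S = S,
                    got = got, want = want))
      }
    }
  }
  list(ok = TRUE)
}

# Deterministic grid-integration posterior for the one-probe hierarchical
# model: p(mu, tau | y) integrated numerically, theta means by conjugacy.
grid_posterior <- function(y, se, mu_prior_sd = 10, tau_prior_scale = 2.5,
                           mu_grid = seq(-6, 8, length.out = 500),
                           tau_grid = seq(1e-4, 8, length.out = 600)) {
  lp <- matrix(0, length(mu_grid), length(tau_grid))
  for (j in seq_along(tau_grid)) {
    v <- sqrt(se^2 + tau_grid[j]^2)
    lp[, j] <- vapply(mu_grid, function(m)
      sum(dnorm(y, m, v, log = TRUE)), 0) +
      dnorm(mu_grid, 0, mu_prior_sd, log = TRUE) -
      log1p((tau_grid[j] / tau_prior_scale)^2)
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  wm <- rowSums(w); wt <- colSums(w)
  theta_mean <- vapply(seq_along(y), function(i) {
    tot <- 0
    for (j in seq_along(tau_grid)) {
      shrink <- tau_grid[j]^2 / (tau_grid[j]^2 + se[i]^2)
      tot <- tot + sum(w[, j] * (mu_grid + shrink * (y[i] - mu_grid)))
    }
    tot
  }, 0)
  list(mu_mean = sum(wm * mu_grid),
       mu_sd = sqrt(sum(wm * mu_grid^2) - sum(wm * mu_grid)^2),
       tau_mean = sum(wt * tau_grid),
       theta_mean = theta_mean)
}

# One-probe group-estimate tibble for sampler tests.
fake_estimates <- function(y, se, probe_id = "p1") {
  tibble::tibble(probe_id = probe_id, dose_level = "low",
                 time_value = seq_along(y), time_unit = "hour",
                 y = y, se = se)
}

# Rank-average quantile normalization oracle (mean of order statistics;
# ties get the mean reference value of their tied ranks).
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (ref[lo] + ref[hi]) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

# Hand-built posterior difference for decision-rule tests.
fake_diff <- function(median, hdi_low, hdi_high, draws = NULL,
                      probe_id = "p1") {
  out <- tibble::tibble(probe_id = probe_id, group_id = "high@24hour",
                        control_id = "control@24hour",
                        median = as.numeric(median),
                        hdi_low = as.numeric(hdi_low),
                        hdi_high = as.numeric(hdi_high))
  attr(out, "draws") <- draws
  attr(out, "mass") <- 0.95
  class(out) <- c("posterior_diff", class(out))
  out
}

# Small synthetic intensity matrix with ids.
fake_matrix <- function(values) {
  values <- as.matrix(values)
  dimnames(values) <- list(paste0("p", seq_len(nrow(values))),
                           paste0("s", seq_len(ncol(values))))
  expr_matrix(values, scale = "intensity")
}
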