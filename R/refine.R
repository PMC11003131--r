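# Iterative parametrization: simulate the CG model, compare its bonded
# distributions to target (all-atom, mapped) distributions, update the
# harmonic parameters by damped moment matching, repeat to convergence.
#
# For harmonic terms the two moments are sufficient statistics, so matching
# moments is equivalent to (and far better conditioned than) histogram-level
# iterative Boltzmann inversion:
#   r0 <- r0 + damping * (mu_target - mu_cg)
#   k  <- k * (var_cg / var_target)^damping
# (the variance ratio is unitless, so the same update serves bonds and
# angles; the convergence measure is the base-2 Jensen-Shannon divergence.)

#' Place a chain/tree topology at its force-field equilibrium geometry
#'
#' Deterministic starting structure for refinement runs: beads are laid out
#' bond by bond at the equilibrium lengths and angles (planar zig-zag for
#' unconstrained torsions).
#'
#' @param topology a [cg_topology()] whose bond graph is a chain or tree.
#' @param ff a [force_field()] with parameters for every term.
#' @return a `cg_frame`.
#' @export
build_initial_frame <- function(topology, ff) {
  pars <- collect_params(ff, topology)
  n <- length(topology$beads)
  X <- matrix(NA_real_, n, 3)
  adj <- bond_adjacency(topology)
  order <- tree_order(adj, n)
  X[order$root, ] <- c(0, 0, 0)
  for (idx in seq_along(order$children)) {
    child <- order$children[idx]; parent <- order$parents[idx]
    bk <- bond_key(parent, child)
    r <- pars$bond[[match(bk, pars$keys$bonds)]]$equilibrium
    gp <- order$grandparents[idx]
    if (is.na(gp)) {
      X[child, ] <- X[parent, ] + c(r, 0, 0)
    } else {
      ak <- angle_key(gp, parent, child)
      i <- match(ak, pars$keys$angles)
      th <- if (is.na(i)) 120 else pars$angle[[i]]$equilibrium
      w <- X[gp, ] - X[parent, ]
      w <- w / sqrt(sum(w^2))
      e1 <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      e1 <- e1 - sum(e1 * w) * w
      e1 <- e1 / sqrt(sum(e1^2))
      d <- cos(th * pi / 180) * w + sin(th * pi / 180) * e1
      X[child, ] <- X[parent, ] + r * d
    }
  }
  new_frame(X, time = 0)
}

bond_adjacency <- function(topology) {
  n <- length(topology$beads)
  adj <- vector("list", n)
  bt <- topology$bond_terms
  for (r in seq_len(nrow(bt))) {
    adj[[bt[r, 1]]] <- c(adj[[bt[r, 1]]], bt[r, 2])
    adj[[bt[r, 2]]] <- c(adj[[bt[r, 2]]], bt[r, 1])
  }
  adj
}

# BFS order over a chain/tree bond graph; errors on cycles.
tree_order <- function(adj, n) {
  root <- 1L
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  visited[root] <- TRUE
  queue <- root
  children <- integer(0); parents <- integer(0); grandparents <- integer(0)
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (nb == parent[cur] && !is.na(parent[cur])) next
      if (visited[nb])
        stop("chain/tree required: bond graph contains a cycle", call. = FALSE)
      visited[nb] <- TRUE
      parent[nb] <- cur
      children <- c(children, nb); parents <- c(parents, cur)
      grandparents <- c(grandparents, parent[cur])
      queue <- c(queue, nb)
    }
  }
  if (!all(visited))
    stop("bond graph must be connected (chain/tree required)", call. = FALSE)
  list(root = root, children = children, parents = parents,
       grandparents = grandparents)
}

#' Refine CG parameters against target bonded distributions
#'
#' Each iteration (i) runs [run_dynamics()] with the current parameters
#' (iteration `i` uses seed `config$seed + i`), (ii) measures the CG bonded
#' distributions, (iii) computes the per-term Jensen-Shannon divergence to
#' the targets, and (iv) if any divergence exceeds `threshold`, applies the
#' damped moment-matching update. The loop stops as soon as all divergences
#' are at or below `threshold` — without applying a further update, so
#' `final_force_field` is exactly the parameter set whose divergences were
#' verified — or when `max_iterations` is reached.
#'
#' @param target_dists named list of `bonded_distribution` objects keyed by
#'   canonical term key (as produced by `measure_all_terms`); must cover
#'   every bonded term of `topology`.
#' @param initial_ff starting [force_field()].
#' @param topology the [cg_topology()].
#' @param engine_config an [engine_config()] used for each iteration's
#'   sampling run.
#' @param masses bead masses, amu.
#' @param threshold per-term divergence threshold (default 0.02 bits).
#' @param max_iterations iteration cap (default 20).
#' @param damping update damping in (0, 1] (default 0.5).
#' @param initial_frame optional starting `cg_frame`; default is the
#'   equilibrium layout of [build_initial_frame()].
#' @param divergence_bins bins for [distribution_divergence()].
#' @return an object of class `convergence_report`: `iterations_run`,
#'   `divergence_history` (matrix, iterations x terms), `converged`,
#'   `threshold`, `final_force_field`, `parameter_history`.
#' @export
refine_parameters <- function(target_dists, initial_ff, topology,
                              engine_config, masses, threshold = 0.02,
                              max_iterations = 20, damping = 0.5,
                              initial_frame = NULL, divergence_bins = 60) {
  .assert(damping > 0 && damping <= 1, "damping must be in (0, 1]")
  .assert(max_iterations >= 0, "max_iterations must be >= 0")
  tk <- term_keys(topology)
  keys <- c(tk$bonds, tk$angles)
  for (k in keys)
    .assert(!is.null(target_dists[[k]]), "no target distribution for term %s", k)
  ff <- initial_ff
  collect_params(ff, topology)  # completeness check up front
  if (is.null(initial_frame)) initial_frame <- build_initial_frame(topology, ff)

  history <- matrix(numeric(0), nrow = 0, ncol = length(keys),
                    dimnames = list(NULL, keys))
  param_hist <- list()
  converged <- FALSE
  iterations <- 0

  while (iterations < max_iterations) {
    iterations <- iterations + 1
    cfg <- engine_config
    cfg$seed <- engine_config$seed + iterations
    res <- tryCatch(
      run_dynamics(initial_frame, ff, topology, cfg, masses),
      error = function(e) stop(sprintf("iteration %d: %s", iterations,
                                       conditionMessage(e)), call. = FALSE))
    # drop the initial frame: it is a deterministic construction, not a
    # sample of the bonded marginals
    cg_dists <- measure_all_terms(strip_first_frame(res$trajectory), topology)

    div <- vapply(keys, function(k)
      distribution_divergence(target_dists[[k]], cg_dists[[k]],
                              n_bins = divergence_bins), numeric(1))
    history <- rbind(history, div)
    param_hist[[iterations]] <- ff

    if (all(div <= threshold)) { converged <- TRUE; break }

    for (k in tk$bonds) {
      if (!(cg_dists[[k]]$variance > 0))
        stop(sprintf("iteration %d: zero sampled variance for term %s",
                     iterations, k), call. = FALSE)
      p <- ff$bond_params[[k]]
      tgt <- target_dists[[k]]
      ff$bond_params[[k]] <- harmonic_params(
        equilibrium = p$equilibrium + damping * (tgt$mean - cg_dists[[k]]$mean),
        force_constant = p$force_constant *
          (cg_dists[[k]]$variance / tgt$variance)^damping,
        kind = "bond")
    }
    for (k in tk$angles) {
      if (!(cg_dists[[k]]$variance > 0))
        stop(sprintf("iteration %d: zero sampled variance for term %s",
                     iterations, k), call. = FALSE)
      p <- ff$angle_params[[k]]
      tgt <- target_dists[[k]]
      ff$angle_params[[k]] <- harmonic_params(
        equilibrium = p$equilibrium + damping * (tgt$mean - cg_dists[[k]]$mean),
        force_constant = p$force_constant *
          (cg_dists[[k]]$variance / tgt$variance)^damping,
        kind = "angle")
    }
  }
  rownames(history) <- NULL
  structure(list(iterations_run = iterations,
                 divergence_history = history,
                 converged = converged, threshold = threshold,
                 final_force_field = ff,
                 parameter_history = param_hist),
            class = "convergence_report")
}

strip_first_frame <- function(traj) {
  if (traj$n_frames <= 1) return(traj)
  new_trajectory(traj$coords[, , -1, drop = FALSE], times = traj$times[-1],
                 box = if (is.null(traj$box)) NULL else
                   traj$box[-1, , drop = FALSE])
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("convergence_report: %d iterations, %s (threshold %.3g)\n",
              x$iterations_run,
              if (x$converged) "converged" else "not converged", x$threshold))
  if (nrow(x$divergence_history) > 0) {
    last <- x$divergence_history[nrow(x$divergence_history), ]
    cat("final divergences:",
        paste(sprintf("%s = %.4f", names(last), last), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a convergence report as tabular text
#'
#' @param report a `convergence_report`.
#' @param path optional output path (TSV).
#' @return a data.frame with one row per iteration and term.
#' @export
report_table <- function(report, path = NULL) {
  h <- report$divergence_history
  df <- data.frame(iteration = rep(seq_len(nrow(h)), times = ncol(h)),
                   term = rep(colnames(h), each = nrow(h)),
                   divergence = as.vector(h), stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
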