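#' BIC local score of one node given a parent set
#'
#' Maximum log-likelihood of the child's conditional Bernoulli distribution
#' given every configuration of its parents, penalised by
#' `(k / 2) * log(n)` with `k = 2^|parents|` free parameters. Local scores
#' are decomposable, so the network score is their sum over nodes.
#'
#' @param fm an `mn_feature_matrix`.
#' @param child feature name.
#' @param parents character vector of parent feature names (may be empty).
#' @return the local BIC score (log scale; larger is better).
#' @export
bic_score <- function(fm, child, parents = character(0)) {
  stopifnot(inherits(fm, "mn_feature_matrix"))
  unknown <- setdiff(c(child, parents), fm$feature_names)
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (child %in% parents) stop("child cannot be its own parent", call. = FALSE)
  x <- fm$x
  n <- nrow(x)
  y <- x[, child]
  if (length(parents)) {
    cfg <- as.integer(x[, parents, drop = FALSE] %*%
                        2^(seq_along(parents) - 1))
    n1 <- tapply(y, cfg, sum)
    ntot <- tapply(y, cfg, length)
  } else {
    n1 <- sum(y); ntot <- n
  }
  n0 <- ntot - n1
  xlogx <- function(a) ifelse(a > 0, a * log(a), 0)
  ll <- sum(xlogx(n1) + xlogx(n0) - xlogx(ntot))
  ll - (2^length(parents) / 2) * log(n)
}

#' Learn a Bayesian-network structure by hill climbing
#'
#' Greedy score-based search over directed acyclic graphs with add / delete /
#' reverse moves and the BIC score ([bic_score()]); the best-scoring network
#' over `restarts` randomised starting graphs is returned. The in-degree of
#' every node is capped at `max_in_degree`. Edge orientation from
#' observational binary data is generally not identifiable, so downstream
#' comparisons should use the undirected skeleton.
#'
#' @param fm an `mn_feature_matrix` with at least two features and 20
#'   patients.
#' @param max_in_degree maximum number of parents per node.
#' @param restarts number of random restarts (the first start is the empty
#'   graph).
#' @param seed integer seed; the search is deterministic given it.
#' @return object of class `mn_dag`: list with `nodes`, `edges` (two-column
#'   character matrix, parent then child), `score`, and `adjacency`.
#' @export
hill_climb_structure <- function(fm, max_in_degree = 3, restarts = 10, seed) {
  stopifnot(inherits(fm, "mn_feature_matrix"))
  d <- ncol(fm$x)
  if (d < 2L) stop("need at least two features", call. = FALSE)
  if (nrow(fm$x) < 20L) stop("need at least 20 patients", call. = FALSE)
  feats <- fm$feature_names
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)

  cache <- new.env(parent = emptyenv())
  local_score <- function(child_i, parent_idx) {
    key <- paste0(child_i, "|", paste(sort(parent_idx), collapse = ","))
    val <- cache[[key]]
    if (is.null(val)) {
      val <- bic_score(fm, feats[child_i], feats[parent_idx])
      cache[[key]] <- val
    }
    val
  }

  has_path <- function(adj, from, to) {        # reachability from -> to
    seen <- logical(d); stack <- from
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v == to) return(TRUE)
      if (!seen[v]) {
        seen[v] <- TRUE
        stack <- c(stack, which(adj[v, ]))
      }
    }
    FALSE
  }

  climb <- function(adj) {
    sc <- vapply(seq_len(d), function(j) local_score(j, which(adj[, j])),
                 numeric(1))
    repeat {
      best_gain <- 1e-9; best <- NULL
      for (u in seq_len(d)) for (v in seq_len(d)) {
        if (u == v) next
        if (adj[u, v]) {
          # delete u -> v
          gain <- local_score(v, setdiff(which(adj[, v]), u)) - sc[v]
          if (gain > best_gain) { best_gain <- gain; best <- c(1L, u, v) }
          # reverse u -> v (becomes v -> u)
          if (sum(adj[, u]) < max_in_degree) {
            adj[u, v] <- FALSE
            ok <- !has_path(adj, u, v)
            adj[u, v] <- TRUE
            if (ok) {
              gain <- (local_score(v, setdiff(which(adj[, v]), u)) - sc[v]) +
                      (local_score(u, c(which(adj[, u]), v)) - sc[u])
              if (gain > best_gain) { best_gain <- gain; best <- c(2L, u, v) }
            }
          }
        } else if (sum(adj[, v]) < max_in_degree &&
                   !adj[v, u] && !has_path(adj, v, u)) {
          # add u -> v
          gain <- local_score(v, c(which(adj[, v]), u)) - sc[v]
          if (gain > best_gain) { best_gain <- gain; best <- c(0L, u, v) }
        }
      }
      if (is.null(best)) break
      u <- best[2]; v <- best[3]
      if (best[1] == 0L) adj[u, v] <- TRUE
      else if (best[1] == 1L) adj[u, v] <- FALSE
      else { adj[u, v] <- FALSE; adj[v, u] <- TRUE }
      sc[v] <- local_score(v, which(adj[, v]))
      if (best[1] == 2L) sc[u] <- local_score(u, which(adj[, u]))
    }
    list(adj = adj, score = sum(sc))
  }

  random_start <- function() {
    ord <- sample.int(d)
    adj <- matrix(FALSE, d, d)
    for (j in 2:d) {
      anc <- ord[seq_len(j - 1)]
      pick <- anc[stats::runif(length(anc)) < 0.05]
      pick <- utils::head(pick, max_in_degree)
      adj[pick, ord[j]] <- TRUE
    }
    adj
  }

  best <- climb(matrix(FALSE, d, d))
  if (restarts > 1) for (r in seq_len(restarts - 1)) {
    cand <- climb(random_start())
    if (cand$score > best$score) best <- cand
  }
  edges <- which(best$adj, arr.ind = TRUE)
  structure(list(nodes = feats,
                 edges = cbind(parent = feats[edges[, 1]],
                               child = feats[edges[, 2]]),
                 score = best$score,
                 adjacency = best$adj),
            class = "mn_dag")
}

#' @export
print.mn_dag <- function(x, ...) {
  cat(sprintf("<mn_dag: %d nodes, %d edges, BIC score %.2f>\n",
              length(x$nodes), nrow(x$edges), x$score))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2], collapse = "\n"),
        "\n")
  invisible(x)
}

#' Undirected skeleton of a learned network
#'
#' @param dag an `mn_dag`.
#' @return two-column character matrix of unordered edges (lexicographic).
#' @export
dag_skeleton <- function(dag) {
  stopifnot(inherits(dag, "mn_dag"))
  if (!nrow(dag$edges))
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("a", "b"))))
  e <- t(apply(dag$edges, 1, sort))
  e <- unique(e)
  colnames(e) <- c("a", "b")
  e
}

# save/restore the global RNG state so seeded internals do not disturb the
# caller's random stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
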