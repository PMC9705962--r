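# Community interaction network: a directed acyclic graph whose nodes are
# diet features, taxa at the initial timepoint (t0), and taxa at the final
# timepoint (t1). Only t1 taxa may have parents (diet and t0 nodes are
# roots), a taxon never parents itself at t1, and in-degree is capped.
# Node names carry a layer prefix: "diet:", "t0:", "t1:".

#' Construct a community interaction network
#'
#' @param diet_features Character vector of diet feature names.
#' @param taxa Character vector of taxon names.
#' @param parents Named list, one entry per taxon (the `t1` child), each a
#'   character vector of parent node names with layer prefixes `"diet:"`,
#'   `"t0:"` or `"t1:"`. Missing taxa get empty parent sets.
#' @param max_parents In-degree cap (default 5).
#' @return An `interaction_network` object.
#' @export
interaction_network <- function(diet_features, taxa, parents = list(),
                                max_parents = 5) {
  full <- stats::setNames(
    lapply(taxa, function(tx) {
      p <- parents[[tx]]
      if (is.null(p)) character(0) else as.character(p)
    }),
    taxa
  )
  net <- structure(
    list(diet_features = diet_features, taxa = taxa, parents = full,
      max_parents = max_parents),
    class = "interaction_network"
  )
  validate_network(net)
  net
}

#' Validate the structural invariants of an interaction network
#'
#' Checks that all parents are known nodes, no taxon parents itself at
#' `t1`, in-degrees respect the cap, and the `t1`-layer subgraph is acyclic.
#' Called on every learned or constructed network.
#'
#' @param net An `interaction_network`.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_network <- function(net) {
  valid <- c(paste0("diet:", net$diet_features),
    paste0("t0:", net$taxa), paste0("t1:", net$taxa))
  for (tx in net$taxa) {
    p <- net$parents[[tx]]
    if (length(p) > net$max_parents) {
      stop("taxon '", tx, "' exceeds the in-degree cap of ", net$max_parents)
    }
    if (anyDuplicated(p)) stop("duplicate parents for taxon '", tx, "'")
    bad <- setdiff(p, valid)
    if (length(bad) > 0) {
      stop("unknown parent node(s) for '", tx, "': ", paste(bad, collapse = ", "))
    }
    if (paste0("t1:", tx) %in% p) {
      stop("taxon '", tx, "' cannot parent itself at time t")
    }
  }
  topological_order(net)  # errors on a t1-layer cycle
  invisible(TRUE)
}

#' Topological order of the t1-layer subgraph
#'
#' @param net An `interaction_network`.
#' @return Character vector of taxon names ordered so that every taxon's
#'   `t1` parents precede it.
#' @export
topological_order <- function(net) {
  deps <- lapply(net$parents, function(p) {
    sub("^t1:", "", p[startsWith(p, "t1:")])
  })
  order <- character(0)
  remaining <- net$taxa
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(tx) {
      all(deps[[tx]] %in% order)
    }, logical(1))]
    if (length(ready) == 0) {
      stop("cycle detected among time-t taxa: ", paste(remaining, collapse = ", "))
    }
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Edge list of an interaction network
#'
#' @param net An `interaction_network`.
#' @return Data frame with columns `parent`, `child`, `layer` (the parent's
#'   layer: `diet`, `t0` or `t1`); zero rows for an empty network.
#' @export
network_edges <- function(net) {
  rows <- lapply(net$taxa, function(tx) {
    p <- net$parents[[tx]]
    if (length(p) == 0) return(NULL)
    data.frame(parent = p, child = tx, layer = sub(":.*", "", p),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(parent = character(0), child = character(0),
      layer = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Diet features participating in a network
#'
#' @param net An `interaction_network`.
#' @return Character vector of the diet features that parent at least one
#'   taxon.
#' @export
network_diet_nodes <- function(net) {
  e <- network_edges(net)
  sort(unique(sub("^diet:", "", e$parent[e$layer == "diet"])))
}

#' @export
print.interaction_network <- function(x, ...) {
  e <- network_edges(x)
  cat("Community interaction network:", length(x$taxa), "taxa,",
    length(x$diet_features), "diet features,", nrow(e), "edges\n")
  cat("  parent layers:", paste(names(table(e$layer)),
    table(e$layer), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# BIC-style score of one child regression: larger is better. Gaussian
# linear model of the child on its parents, intercept always included.
child_score <- function(y, xmat, pset) {
  n <- length(y)
  x <- cbind(1, xmat[, pset, drop = FALSE])
  fit <- stats::.lm.fit(x, y)
  rss <- sum(fit$residuals^2)
  -(n * log(max(rss, 1e-10) / n) + ncol(x) * log(n))
}

#' Learn a community interaction network by greedy score-based search
#'
#' Hill climbing over single-edge additions, deletions and (taxon-taxon)
#' reversals, maximizing the sum over taxa of a BIC-penalized Gaussian
#' linear-regression score of each `t1` taxon on its parents. The search
#' respects the structural constraints: diet and `t0` nodes never acquire
#' parents, no `t1` self-edges, in-degree at most `max_parents`, and the
#' `t1` subgraph stays acyclic. Random restarts (the first from the empty
#' network, the rest from random sparse DAGs) guard against local optima;
#' the best-scoring result is returned. Deterministic given `seed`.
#'
#' @param data A `paired_data` object (see [paired_data()]).
#' @param max_parents In-degree cap (default 5).
#' @param restarts Number of search starts (default 10).
#' @param seed Integer seed for the random restarts.
#' @return An `interaction_network` with attribute `"score"`.
#' @export
learn_interaction_network <- function(data, max_parents = 5, restarts = 10,
                                      seed = 1) {
  stopifnot(inherits(data, "paired_data"))
  if (data$n < 2) stop("need at least 2 observations")
  taxa <- colnames(data$t1)
  vals <- cbind(
    `colnames<-`(data$diet, paste0("diet:", colnames(data$diet))),
    `colnames<-`(data$t0, paste0("t0:", colnames(data$t0))),
    `colnames<-`(data$t1, paste0("t1:", colnames(data$t1)))
  )
  const <- apply(vals, 2, function(v) max(v) - min(v) < 1e-12)
  if (any(const)) {
    warning("constant variable(s) excluded from candidate parents: ",
      paste(colnames(vals)[const], collapse = ", "))
  }
  usable <- colnames(vals)[!const]
  candidates <- stats::setNames(lapply(taxa, function(tx) {
    setdiff(usable, paste0("t1:", tx))
  }), taxa)

  run_greedy <- function(parents) {
    cur <- vapply(taxa, function(tx) {
      child_score(data$t1[, tx], vals, parents[[tx]])
    }, numeric(1))
    add_delta <- stats::setNames(vector("list", length(taxa)), taxa)
    del_delta <- stats::setNames(vector("list", length(taxa)), taxa)
    refresh <- function(tx) {
      pset <- parents[[tx]]
      adds <- setdiff(candidates[[tx]], pset)
      add_delta[[tx]] <<- vapply(adds, function(p) {
        child_score(data$t1[, tx], vals, c(pset, p)) - cur[[tx]]
      }, numeric(1))
      del_delta[[tx]] <<- vapply(pset, function(p) {
        child_score(data$t1[, tx], vals, setdiff(pset, p)) - cur[[tx]]
      }, numeric(1))
    }
    for (tx in taxa) refresh(tx)

    # would adding edge t1:from -> to create a cycle (from reachable from to)?
    reaches <- function(src, dst, skip_child = NULL, skip_parent = NULL) {
      stack <- src
      seen <- character(0)
      while (length(stack) > 0) {
        node <- stack[[1]]
        stack <- stack[-1]
        if (node == dst) return(TRUE)
        if (node %in% seen) next
        seen <- c(seen, node)
        p <- parents[[node]]
        if (!is.null(skip_child) && node == skip_child) {
          p <- setdiff(p, paste0("t1:", skip_parent))
        }
        stack <- c(stack, sub("^t1:", "", p[startsWith(p, "t1:")]))
      }
      FALSE
    }

    repeat {
      best <- list(delta = 1e-9, move = NULL)
      for (tx in taxa) {
        if (length(parents[[tx]]) < max_parents) {
          for (p in names(add_delta[[tx]])) {
            d <- add_delta[[tx]][[p]]
            if (d > best$delta) {
              if (startsWith(p, "t1:") &&
                  reaches(sub("^t1:", "", p), tx)) next
              best <- list(delta = d, move = list("add", tx, p))
            }
          }
        }
        for (p in names(del_delta[[tx]])) {
          d <- del_delta[[tx]][[p]]
          if (d > best$delta) best <- list(delta = d, move = list("del", tx, p))
        }
      }
      # reversals of t1 -> t1 edges: delete p->tx, add tx->p
      for (tx in taxa) {
        for (p in parents[[tx]][startsWith(parents[[tx]], "t1:")]) {
          ptax <- sub("^t1:", "", p)
          back <- paste0("t1:", tx)
          if (length(parents[[ptax]]) >= max_parents) next
          if (!back %in% names(add_delta[[ptax]])) next
          d <- del_delta[[tx]][[p]] + add_delta[[ptax]][[back]]
          if (d > best$delta) {
            if (reaches(tx, ptax, skip_child = tx, skip_parent = ptax)) next
            best <- list(delta = d, move = list("rev", tx, p))
          }
        }
      }
      if (is.null(best$move)) break
      mv <- best$move
      if (mv[[1]] == "add") {
        parents[[mv[[2]]]] <- c(parents[[mv[[2]]]], mv[[3]])
        dirty <- mv[[2]]
      } else if (mv[[1]] == "del") {
        parents[[mv[[2]]]] <- setdiff(parents[[mv[[2]]]], mv[[3]])
        dirty <- mv[[2]]
      } else {
        ptax <- sub("^t1:", "", mv[[3]])
        parents[[mv[[2]]]] <- setdiff(parents[[mv[[2]]]], mv[[3]])
        parents[[ptax]] <- c(parents[[ptax]], paste0("t1:", mv[[2]]))
        dirty <- c(mv[[2]], ptax)
      }
      for (tx in dirty) {
        cur[[tx]] <- child_score(data$t1[, tx], vals, parents[[tx]])
        refresh(tx)
      }
    }
    list(parents = parents, score = sum(cur))
  }

  random_start <- function() {
    parents <- stats::setNames(rep(list(character(0)), length(taxa)), taxa)
    order_t1 <- sample(taxa)
    for (q in seq_along(order_t1)) {
      tx <- order_t1[q]
      pool <- intersect(candidates[[tx]], c(
        usable[!startsWith(usable, "t1:")],
        paste0("t1:", order_t1[seq_len(q - 1)])
      ))
      k <- min(sample(0:2, 1), length(pool), max_parents)
      if (k > 0) parents[[tx]] <- sample(pool, k)
    }
    parents
  }

  empty <- stats::setNames(rep(list(character(0)), length(taxa)), taxa)
  best <- NULL
  with_seed(sub_seed(seed, "structure_search"), {
    for (r in seq_len(max(1, restarts))) {
      start <- if (r == 1) empty else random_start()
      res <- run_greedy(start)
      if (is.null(best) || res$score > best$score + 1e-9) best <- res
    }
  })
  net <- interaction_network(colnames(data$diet), taxa, best$parents,
    max_parents = max_parents)
  attr(net, "score") <- best$score
  net
}

#' Total score of a network on a dataset
#'
#' Sum over taxa of the BIC-penalized Gaussian regression score used by
#' [learn_interaction_network()]; useful for comparing candidate
#' structures.
#'
#' @param net An `interaction_network`.
#' @param data A `paired_data` object.
#' @return A single number; larger is better.
#' @export
network_score <- function(net, data) {
  vals <- cbind(
    `colnames<-`(data$diet, paste0("diet:", colnames(data$diet))),
    `colnames<-`(data$t0, paste0("t0:", colnames(data$t0))),
    `colnames<-`(data$t1, paste0("t1:", colnames(data$t1)))
  )
  sum(vapply(net$taxa, function(tx) {
    child_score(data$t1[, tx], vals, net$parents[[tx]])
  }, numeric(1)))
}
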