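# Symbolic-regression phenotype classifiers: small arithmetic expression
# trees over {+, -, *, protected /}, feature variables and constants,
# evolved by genetic programming against 0/1 phenotype labels with a
# complexity-aware Pareto front. Predictions threshold the function value
# at 0.5.

OPS <- c("+", "-", "*", "/")

expr_const <- function(value) list(type = "const", value = value)
expr_var <- function(name) list(type = "var", name = name)
expr_op <- function(op, l, r) list(type = "op", op = op, l = l, r = r)

#' Evaluate an expression tree on a feature matrix
#'
#' Division is protected: where the denominator is within 1e-9 of zero the
#' quotient is defined as 1, so every expression evaluates to a finite
#' value on finite input.
#'
#' @param expr Expression tree (as stored in a `phenotype_model`).
#' @param features Matrix or data frame (samples x features) with named
#'   columns.
#' @return Numeric vector of function values, one per sample.
#' @export
eval_expression <- function(expr, features) {
  n <- nrow(features)
  rec <- function(e) {
    switch(e$type,
      const = rep(e$value, n),
      var = {
        if (!e$name %in% colnames(features)) {
          stop("missing feature: '", e$name, "'")
        }
        features[, e$name]
      },
      op = {
        a <- rec(e$l)
        b <- rec(e$r)
        switch(e$op,
          `+` = a + b,
          `-` = a - b,
          `*` = a * b,
          `/` = ifelse(abs(b) < 1e-9, 1, a / b))
      })
  }
  rec(expr)
}

expr_complexity <- function(e) {
  if (e$type == "op") 1L + expr_complexity(e$l) + expr_complexity(e$r) else 1L
}

#' Render an expression tree as an infix string
#' @param expr Expression tree.
#' @return Character scalar.
#' @export
render_expression <- function(expr) {
  rec <- function(e) {
    switch(e$type,
      const = format(e$value, digits = 4),
      var = e$name,
      op = paste0("(", rec(e$l), " ", e$op, " ", rec(e$r), ")"))
  }
  rec(expr)
}

# --- tree surgery -----------------------------------------------------------

get_subtree <- function(e, idx) {
  env <- new.env()
  env$i <- 0L
  env$hit <- NULL
  rec <- function(node) {
    env$i <- env$i + 1L
    if (env$i == idx) {
      env$hit <- node
      return(invisible(NULL))
    }
    if (node$type == "op" && is.null(env$hit)) {
      rec(node$l)
      if (is.null(env$hit)) rec(node$r)
    }
    invisible(NULL)
  }
  rec(e)
  env$hit
}

set_subtree <- function(e, idx, repl) {
  env <- new.env()
  env$i <- 0L
  rec <- function(node) {
    env$i <- env$i + 1L
    if (env$i == idx) return(repl)
    if (node$type == "op") {
      node$l <- rec(node$l)
      node$r <- rec(node$r)
    }
    node
  }
  rec(e)
}

random_terminal <- function(features) {
  if (stats::runif(1) < 0.6) {
    expr_var(sample(features, 1))
  } else if (stats::runif(1) < 0.5) {
    expr_const(sample(c(0, 1), 1))
  } else {
    expr_const(stats::runif(1, -2, 2))
  }
}

random_tree <- function(features, depth, full = FALSE) {
  if (depth <= 0 || (!full && stats::runif(1) < 0.3)) {
    return(random_terminal(features))
  }
  expr_op(sample(OPS, 1),
    random_tree(features, depth - 1, full),
    random_tree(features, depth - 1, full))
}

point_mutate <- function(e, features) {
  idx <- sample(expr_complexity(e), 1)
  node <- get_subtree(e, idx)
  repl <- if (node$type == "op") {
    node$op <- sample(OPS, 1)
    node
  } else if (node$type == "const" && stats::runif(1) < 0.5) {
    # jitter rather than replace: lets the search fine-tune constants
    expr_const(max(-2, min(2, node$value + stats::rnorm(1, 0, 0.25))))
  } else {
    random_terminal(features)
  }
  set_subtree(e, idx, repl)
}

subtree_mutate <- function(e, features) {
  idx <- sample(expr_complexity(e), 1)
  set_subtree(e, idx, random_tree(features, 2))
}

crossover <- function(a, b) {
  ia <- sample(expr_complexity(a), 1)
  ib <- sample(expr_complexity(b), 1)
  set_subtree(a, ia, get_subtree(b, ib))
}

# --- evolution --------------------------------------------------------------

pareto_front <- function(archive) {
  if (length(archive) == 0) return(archive)
  cx <- as.integer(names(archive))
  ord <- order(cx)
  best <- Inf
  keep <- list()
  for (i in ord) {
    err <- archive[[i]]$error
    if (err < best - 1e-15) {
      keep[[as.character(cx[i])]] <- archive[[i]]
      best <- err
    }
  }
  keep
}

#' Evolve a symbolic phenotype classifier
#'
#' Genetic programming over arithmetic expression trees: tournament
#' selection on a parsimony-penalized mean-squared error against the 0/1
#' labels, subtree crossover, and point/subtree mutation, with elitism.
#' Every evaluated individual updates a (complexity, error) Pareto
#' archive. The run stops when, over the last `window` generations, the
#' front's best error was effectively unchanged in at least `stability`
#' percent of them and at least `convergence` percent of front members
#' were unchanged generation-to-generation - or at the generation cap.
#' The returned model is the least-complex front member within 1% of the
#' best front error.
#'
#' @param features Matrix (samples x features) with named columns.
#' @param labels Binary 0/1 vector, one per sample.
#' @param pop_size Population size (default 200).
#' @param generations Generation cap (default 200).
#' @param parsimony Complexity penalty added to the selection fitness per
#'   expression node (default 0.001); the Pareto front itself uses raw
#'   error.
#' @param seed Integer seed; identical seed and config give an identical
#'   model.
#' @param target `"OBESITY"` or `"DIET"` (metadata only).
#' @param stability,convergence Termination thresholds in percent
#'   (default 95).
#' @param window Generations over which stability and convergence are
#'   assessed (default 50).
#' @param max_depth Depth cap for generated subtrees (default 6).
#' @return List with `model` (a `phenotype_model`: `expr`, `features`,
#'   `target`, `complexity`, `train_error`, `expression` string) and
#'   `report` (front as a data frame, `generations`, `stability`,
#'   `convergence`).
#' @export
evolve_classifier <- function(features, labels, pop_size = 200,
                              generations = 200, parsimony = 0.001,
                              seed = 1, target = "OBESITY",
                              stability = 95, convergence = 95,
                              window = 50, max_depth = 6) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (any(!is.finite(features))) stop("features must be finite")
  if (length(unique(labels)) < 2) {
    warning("single-class labels: a constant expression is sufficient")
  }
  fnames <- colnames(features)
  if (is.null(fnames)) stop("feature matrix must have column names")

  mse <- function(e) {
    v <- eval_expression(e, features)
    out <- mean((v - labels)^2)
    if (!is.finite(out)) Inf else out
  }

  with_seed(sub_seed(seed, "evolve"), {
    # seeds: every bare feature, the 0/1 constants, and soft-threshold
    # surfaces (1 +/- x)/2 per feature, whose value crosses 0.5 at x = 0
    half_up <- function(v) {
      expr_op("/", expr_op("+", expr_const(1), expr_var(v)), expr_const(2))
    }
    half_dn <- function(v) {
      expr_op("/", expr_op("-", expr_const(1), expr_var(v)), expr_const(2))
    }
    pop <- c(
      lapply(fnames, expr_var),
      list(expr_const(0), expr_const(1)),
      lapply(fnames, half_up),
      lapply(fnames, half_dn)
    )
    if (length(pop) > pop_size) {
      pop <- pop[seq_len(pop_size)]
    } else {
      while (length(pop) < pop_size) {
        pop[[length(pop) + 1L]] <- random_tree(fnames, sample(2:4, 1),
          full = stats::runif(1) < 0.5)
      }
    }

    archive <- list()
    errs <- comp <- numeric(pop_size)
    evaluate <- function() {
      for (i in seq_len(pop_size)) {
        errs[i] <<- mse(pop[[i]])
        comp[i] <<- expr_complexity(pop[[i]])
        key <- as.character(comp[i])
        if (is.null(archive[[key]]) || errs[i] < archive[[key]]$error) {
          archive[[key]] <<- list(error = errs[i], expr = pop[[i]],
            complexity = comp[i])
        }
      }
    }
    evaluate()

    front_sig <- function(fr) {
      vapply(fr, function(m) paste(m$complexity, signif(m$error, 12)),
        character(1))
    }
    best_hist <- numeric(0)
    conv_hist <- numeric(0)
    prev_sig <- front_sig(pareto_front(archive))
    gens_run <- 0L
    stab_pct <- 0
    conv_pct <- 0

    for (g in seq_len(generations)) {
      gens_run <- g
      fitness <- errs + parsimony * comp
      tournament <- function() {
        k <- sample(pop_size, 3)
        k[which.min(fitness[k])]
      }
      newpop <- vector("list", pop_size)
      newpop[[1]] <- pop[[which.min(fitness)]]  # elitism
      i <- 2L
      while (i <= pop_size) {
        u <- stats::runif(1)
        child <- if (u < 0.7) {
          crossover(pop[[tournament()]], pop[[tournament()]])
        } else if (u < 0.9) {
          point_mutate(pop[[tournament()]], fnames)
        } else {
          subtree_mutate(pop[[tournament()]], fnames)
        }
        if (expr_complexity(child) <= 2^(max_depth + 1)) {
          newpop[[i]] <- child
          i <- i + 1L
        }
      }
      pop <- newpop
      evaluate()

      fr <- pareto_front(archive)
      best <- min(vapply(fr, `[[`, numeric(1), "error"))
      sig <- front_sig(fr)
      conv_hist <- c(conv_hist, 100 * mean(sig %in% prev_sig))
      prev_sig <- sig
      best_hist <- c(best_hist, best)
      if (g >= window) {
        recent <- best_hist[(g - window + 1):g]
        stab_pct <- 100 * mean(abs(diff(c(recent[1], recent))) < 1e-6)
        conv_pct <- mean(conv_hist[(g - window + 1):g])
        if (stab_pct >= stability && conv_pct >= convergence) break
      }
    }

    fr <- pareto_front(archive)
    fr_err <- vapply(fr, `[[`, numeric(1), "error")
    best_err <- min(fr_err)
    ok <- fr[fr_err <= best_err + max(0.01 * best_err, 1e-12)]
    pick <- ok[[which.min(vapply(ok, `[[`, numeric(1), "complexity"))]]

    model <- structure(
      list(expr = pick$expr, features = fnames, target = target,
        complexity = pick$complexity, train_error = pick$error,
        expression = render_expression(pick$expr)),
      class = "phenotype_model"
    )
    front_df <- data.frame(
      complexity = vapply(fr, `[[`, numeric(1), "complexity"),
      error = fr_err, row.names = NULL
    )
    front_df <- front_df[order(front_df$complexity), ]
    list(model = model,
      report = list(front = front_df, generations = gens_run,
        stability = stab_pct, convergence = conv_pct))
  })
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("Phenotype classifier for ", x$target, ":\n  f = ", x$expression,
    "\n  complexity ", x$complexity, ", training MSE ",
    format(x$train_error, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Standardize feature columns for classifier evolution
#'
#' Centers and scales each column to zero mean and unit variance
#' (constant columns are left centered only). The evolved expressions use
#' bounded ephemeral constants, so features are standardized before
#' evolution; apply the same transform (with the training statistics, via
#' `center`/`scale_`) to held-out data before calling [classify()].
#'
#' @param features Matrix (samples x features).
#' @param center,scale_ Optional statistics from a reference (training)
#'   set; computed from `features` when omitted.
#' @return Standardized matrix with attributes `center` and `scale`.
#' @export
standardize_features <- function(features, center = NULL, scale_ = NULL) {
  features <- as.matrix(features)
  if (is.null(center)) center <- colMeans(features)
  if (is.null(scale_)) {
    scale_ <- apply(features, 2, stats::sd)
    scale_[scale_ == 0] <- 1
  }
  out <- scale(features, center = center, scale = scale_)
  attr(out, "center") <- center
  attr(out, "scale") <- scale_
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Classify samples with a phenotype model
#'
#' Predicts class 1 where the evolved function value strictly exceeds 0.5
#' and class 0 otherwise (a value of exactly 0.5 is assigned to the
#' negative class).
#'
#' @param model A `phenotype_model`.
#' @param features Matrix (samples x features) containing every feature the
#'   model uses.
#' @return Integer 0/1 vector of predictions.
#' @export
classify <- function(model, features) {
  stopifnot(inherits(model, "phenotype_model"))
  as.integer(eval_expression(model$expr, as.matrix(features)) > 0.5)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; if any factor of
#' the denominator is zero the MCC is defined as 0.
#'
#' @param predicted,observed Binary 0/1 vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
mcc <- function(predicted, observed) {
  predicted <- as.integer(predicted)
  observed <- as.integer(observed)
  if (length(predicted) != length(observed) || length(predicted) == 0) {
    stop("predicted and observed must be non-empty and of equal length")
  }
  tp <- sum(predicted == 1 & observed == 1)
  tn <- sum(predicted == 0 & observed == 0)
  fp <- sum(predicted == 1 & observed == 0)
  fn <- sum(predicted == 0 & observed == 1)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Deterministic stratified train/test split
#'
#' @param labels Binary 0/1 vector (or any two-level vector when
#'   `stratify = TRUE`).
#' @param test_fraction Fraction of samples held out (default 0.2); must be
#'   strictly between 0 and 1.
#' @param seed Integer seed.
#' @param stratify Preserve class ratios (default `TRUE`).
#' @return List with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(labels, test_fraction = 0.2, seed = 1,
                             stratify = TRUE) {
  n <- length(labels)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be strictly between 0 and 1")
  }
  if (n < 5) stop("need at least 5 samples")
  with_seed(sub_seed(seed, "split"), {
    test <- if (stratify) {
      unlist(lapply(unique(labels), function(cl) {
        idx <- which(labels == cl)
        k <- max(1, round(test_fraction * length(idx)))
        if (k >= length(idx)) {
          stop("stratified split impossible: class '", cl,
            "' would vanish from the training set")
        }
        sample(idx, k)
      }), use.names = FALSE)
    } else {
      sample(n, max(1, round(test_fraction * n)))
    }
    list(train = sort(setdiff(seq_len(n), test)), test = sort(test))
  })
}

#' Save / load a phenotype model as JSON
#'
#' @param model A `phenotype_model`.
#' @param path File path.
#' @return `load_phenotype_model`: the restored model.
#' @export
write_phenotype_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phenotype_model
#' @export
load_phenotype_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fix <- function(e) {
    if (e$type == "op") {
      e$l <- fix(e$l)
      e$r <- fix(e$r)
    }
    e
  }
  x$expr <- fix(x$expr)
  x$features <- unlist(x$features)
  structure(x, class = "phenotype_model")
}
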