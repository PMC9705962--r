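# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with recorded ground truth, so all downstream stages are
# testable without any external data. A single integer seed threads through
# all operations; each internal draw uses a named substream so adding one
# generator call does not perturb the others.

#' Full-scale dataset dimensions
#'
#' Dimensions of the real-data setting the generators emulate at full
#' scale: 1558 unique enzyme functions and 2560 metabolites (so that the
#' top 5% of metabolites is 128).
#' @export
full_scale_preset <- function() {
  list(n_ec = 1558L, n_metabolites = 2560L, n_top_metabolites = 128L)
}

#' Simulate a paired diet-response microbiome study
#'
#' Emulates a feeding experiment in which mice raised on a low-fat diet are
#' switched to pellet mixtures spanning a low-fat to high-fat gradient, with
#' the gut community profiled before (`t0`) and after (`t1`) the diet
#' period. Initial communities are Dirichlet-distributed on the sum-100
#' scale; the `t1` log2 abundances are produced by a hidden sparse directed
#' acyclic interaction network whose roots are diet features and `t0` taxa,
#' with uniform \[-1, 1\] edge weights, plus Gaussian noise.
#'
#' @param seed Integer seed; identical seed and sizes regenerate identical
#'   data.
#' @param n_mice Number of mice (paired observations); default 33, giving
#'   66 community states.
#' @param hf_fractions High-fat pellet fractions cycled over the mice
#'   (default the 7-step gradient 0, 1, 10, 25, 50, 75, 100% HF).
#' @param noise_sd Gaussian noise SD on the generated log2 abundances
#'   (default 0.1).
#' @param diet_jitter SD (in units of the 20-80 normalized band) of
#'   per-mouse formulation variability added to each nutrient's
#'   normalized value (default 2, about 3% of the band). Without it all
#'   blended diets collapse onto two exact feature profiles (every
#'   nutrient is an affine function of the mixing fraction), making
#'   multi-nutrient effects unidentifiable.
#' @param parents_per_taxon Parents drawn for each `t1` taxon in the hidden
#'   network (default 2, at most `max_parents`).
#' @param max_parents In-degree cap of the hidden network (default 5).
#' @param pseudocount Log2 pseudocount used throughout (default 0.01).
#' @param renormalize Rescale the noisy `t1` communities to sum 100
#'   (default `TRUE`); the exact pre-normalization log2 abundances are kept
#'   in the ground truth either way.
#' @param vocabulary Taxon vocabulary data frame.
#' @return A `diet_study` list: `diet` (mice x 48 log2 diet features),
#'   `t0` and `t1` (mice x taxa abundance matrices, sum-100),
#'   `hf_fraction`, `mouse_id`, and `truth` with the hidden network
#'   (`interaction_network`), its weights (`map_regression`), the exact
#'   noise-free-scale matrices (`paired_data`), and the seed.
#' @export
simulate_diet_study <- function(seed, n_mice = 33,
                                hf_fractions = c(0, 0.01, 0.10, 0.25, 0.50, 0.75, 1),
                                noise_sd = 0.1, diet_jitter = 2,
                                parents_per_taxon = 2,
                                max_parents = 5, pseudocount = 0.01,
                                renormalize = TRUE,
                                vocabulary = taxon_vocabulary()) {
  if (n_mice < 2) stop("n_mice must be at least 2")
  if (any(hf_fractions < 0 | hf_fractions > 1)) {
    stop("hf_fractions must be in [0, 1]")
  }
  parents_per_taxon <- min(parents_per_taxon, max_parents)
  taxa <- vocabulary$name
  k <- length(taxa)
  mouse_id <- sprintf("mouse%02d", seq_len(n_mice))
  frac <- rep(hf_fractions, length.out = n_mice)

  lf <- reference_diet("LF")
  hf <- reference_diet("HF")
  diet <- t(vapply(frac, function(f) {
    build_diet_vector(blend_diets(lf, hf, f))
  }, numeric(nrow(lf))))
  rownames(diet) <- mouse_id
  if (diet_jitter > 0) {
    diet <- with_seed(sub_seed(seed, "diet_jitter"), {
      pre <- 2^diet + matrix(stats::rnorm(length(diet), sd = diet_jitter),
        nrow(diet), ncol(diet))
      log2(pmin(pmax(pre, 1), 99))
    })
  }

  t0 <- with_seed(sub_seed(seed, "t0"), {
    alpha <- stats::rgamma(k, shape = 2, rate = 2) + 0.1
    g <- matrix(stats::rgamma(n_mice * k, shape = rep(alpha, each = n_mice)),
      n_mice, k, dimnames = list(mouse_id, taxa))
    normalize_community(g)
  })

  # Every taxon keeps a positive-weight edge from its own t0 abundance
  # (communities are temporally persistent over a 7-day window), plus
  # `parents_per_taxon` additional random parents.
  net <- with_seed(sub_seed(seed, "network"), {
    order_t1 <- sample(taxa)
    parents <- stats::setNames(vector("list", k), taxa)
    for (q in seq_len(k)) {
      child <- order_t1[q]
      pool <- c(paste0("diet:", colnames(diet)),
        paste0("t0:", setdiff(taxa, child)))
      if (q > 1) pool <- c(pool, paste0("t1:", order_t1[seq_len(q - 1)]))
      extra <- sample(pool, min(parents_per_taxon, length(pool),
        max_parents - 1))
      parents[[child]] <- c(paste0("t0:", child), extra)
    }
    interaction_network(colnames(diet), taxa, parents)
  })

  t0_log2 <- log2_community(t0, pseudocount)
  target <- log2_community(colMeans(t0), pseudocount)
  coef <- stats::setNames(vector("list", k), taxa)
  x1 <- matrix(0, n_mice, k, dimnames = list(mouse_id, taxa))
  vals <- function(name) {
    tag <- sub(":.*", "", name)
    var <- sub("^[^:]+:", "", name)
    switch(tag, diet = diet[, var], t0 = t0_log2[, var], t1 = x1[, var])
  }
  w_all <- with_seed(sub_seed(seed, "weights"), {
    stats::setNames(lapply(taxa, function(tx) {
      p <- net$parents[[tx]]
      w <- stats::runif(length(p), -1, 1)
      w[p == paste0("t0:", tx)] <- stats::runif(1, 0.5, 1)  # persistence
      w
    }), taxa)
  })
  noise <- with_seed(sub_seed(seed, "noise"), {
    matrix(stats::rnorm(n_mice * k, sd = noise_sd), n_mice, k)
  })
  for (child in topological_order(net)) {
    p <- net$parents[[child]]
    w <- w_all[[child]]
    z <- if (length(p) == 0) rep(0, n_mice) else {
      as.numeric(vapply(p, vals, numeric(n_mice)) %*% w)
    }
    c0 <- target[[child]] - mean(z)
    x1[, child] <- z + c0 + noise[, match(child, taxa)]
    coef[[child]] <- c(intercept = c0, stats::setNames(w, p))
  }

  t1 <- pmax(2^x1 - pseudocount, 0)
  if (renormalize) t1 <- normalize_community(t1)

  truth <- list(
    network = net,
    weights = new_map_regression("network", coef, net$parents,
      colnames(diet), taxa, pseudocount),
    exact = paired_data(diet, t0_log2, x1, pseudocount, log = FALSE),
    noise_sd = noise_sd,
    seed = seed
  )
  structure(
    list(diet = diet, t0 = t0, t1 = t1, hf_fraction = frac,
      mouse_id = mouse_id, pseudocount = pseudocount, truth = truth),
    class = "diet_study"
  )
}

#' Model-ready matrices from a simulated diet study
#'
#' @param study A `diet_study`.
#' @param from_truth Use the exact pre-normalization log2 abundances
#'   recorded in the ground truth instead of re-deriving them from the
#'   (renormalized) observed communities.
#' @return A `paired_data` object.
#' @export
study_paired_data <- function(study, from_truth = FALSE) {
  if (from_truth) return(study$truth$exact)
  paired_data(study$diet, study$t0, study$t1, study$pseudocount)
}

#' Simulate genome annotations and community metagenomes
#'
#' Draws a taxon-by-enzyme-function genome summary (mean gene counts
#' `AveEC`, Poisson-shaped, with SDs proportional to `sqrt(AveEC)`), true
#' per-cell offsets uniform within one SD, Dirichlet communities, and
#' observed enzyme function profiles as community-weighted genome sums plus
#' truncated Gaussian noise.
#'
#' @param seed Integer seed.
#' @param n_taxa,n_ec,n_samples Problem dimensions (the full-scale setting
#'   uses 1558 enzyme functions; see [full_scale_preset()]).
#' @param mean_genes Poisson mean of `AveEC` entries (default 2).
#' @param sd_scale SD entries are `sd_scale * sqrt(AveEC)` (default 0.5).
#' @param noise Relative noise level: Gaussian SD equals `noise` times the
#'   mean predicted EFP value (default 0.05; 0 gives exact community sums).
#' @param taxa Optional taxon names (defaults to the vocabulary when
#'   `n_taxa` is 20, else generic labels).
#' @return List: `genomes` (a `genome_function_matrix`), `offsets` (true
#'   taxon x EC error-term matrix), `communities` (samples x taxa, sum-100),
#'   `efp` (samples x EC observed profiles), `seed`.
#' @export
simulate_metagenome_study <- function(seed, n_taxa = 20, n_ec = 100,
                                      n_samples = 30, mean_genes = 2,
                                      sd_scale = 0.5, noise = 0.05,
                                      taxa = NULL) {
  stopifnot(n_taxa > 0, n_ec > 0, n_samples > 0)
  if (is.null(taxa)) {
    taxa <- if (n_taxa == 20) taxon_vocabulary()$name else
      sprintf("taxon%02d", seq_len(n_taxa))
  }
  ecs <- sprintf("EC%04d", seq_len(n_ec))
  ave <- with_seed(sub_seed(seed, "ave"), {
    matrix(stats::rpois(n_taxa * n_ec, mean_genes), n_taxa, n_ec,
      dimnames = list(taxa, ecs))
  })
  sdm <- sd_scale * sqrt(ave)
  genomes <- genome_function_matrix(ave, sdm)
  offsets <- with_seed(sub_seed(seed, "offsets"), {
    matrix(stats::runif(n_taxa * n_ec, -1, 1), n_taxa, n_ec,
      dimnames = dimnames(ave)) * sdm
  })
  communities <- with_seed(sub_seed(seed, "communities"), {
    alpha <- stats::rgamma(n_taxa, shape = 2, rate = 2) + 0.1
    g <- matrix(stats::rgamma(n_samples * n_taxa,
      shape = rep(alpha, each = n_samples)), n_samples, n_taxa,
      dimnames = list(sprintf("sample%03d", seq_len(n_samples)), taxa))
    normalize_community(g)
  })
  efp <- communities %*% (ave + offsets)
  if (noise > 0) {
    efp <- with_seed(sub_seed(seed, "efp_noise"), {
      efp + matrix(stats::rnorm(length(efp), sd = noise * mean(efp)),
        nrow(efp), ncol(efp))
    })
  }
  efp <- pmax(efp, 0)
  list(genomes = genomes, offsets = offsets, communities = communities,
    efp = efp, seed = seed)
}

#' Simulate a sparse signed enzyme-metabolite reaction network
#'
#' Bipartite links between enzyme functions and the metabolites they
#' produce (`+1`) or consume (`-1`). Every enzyme function gets at least
#' one link; duplicate (EC, metabolite) pairs are not produced.
#'
#' @param seed Integer seed.
#' @param n_ec,n_metabolites Dimensions (full scale: 1558 and 2560).
#' @param mean_degree Mean number of metabolites linked per enzyme
#'   function (default 3; the realized degree is `1 + Poisson(mean_degree - 1)`).
#' @return A data frame with columns `ec`, `metabolite`, `sign`
#'   (class `reaction_network`).
#' @export
simulate_reaction_network <- function(seed, n_ec = 100, n_metabolites = 200,
                                      mean_degree = 3) {
  stopifnot(n_ec > 0, n_metabolites > 0, mean_degree >= 1)
  ecs <- sprintf("EC%04d", seq_len(n_ec))
  mets <- sprintf("M%04d", seq_len(n_metabolites))
  with_seed(sub_seed(seed, "reaction_network"), {
    links <- lapply(seq_len(n_ec), function(i) {
      d <- min(1 + stats::rpois(1, mean_degree - 1), n_metabolites)
      m <- sample(mets, d)
      data.frame(ec = ecs[i], metabolite = m,
        sign = sample(c(-1, 1), d, replace = TRUE),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, links)
    class(out) <- c("reaction_network", "data.frame")
    out
  })
}

#' Simulate a labeled obesity cohort
#'
#' Emulates a cohort of hosts with binary diet (HF/LF) and obesity labels.
#' Communities are Dirichlet draws whose concentration is shifted for
#' high-fat hosts on a random subset of taxa (so diet is predictable from
#' community structure). Observed enzyme function profiles include hidden
#' per-taxon genome offsets and measurement noise; the metabolome is their
#' PRMT scoring through a generated reaction network. The obesity label is
#' the indicator that a hidden sparse linear rule over the metabolome
#' exceeds 0, with label-flip noise - so by construction the metabolome is
#' more informative for obesity than community structure.
#'
#' @param seed Integer seed.
#' @param n_hosts Cohort size (default 54; must be at least 8).
#' @param n_ec,n_metabolites,mean_degree Reaction-network and genome sizes.
#' @param diet_effect Log-scale concentration shift applied to diet-affected
#'   taxa in HF hosts (default 1.5).
#' @param efp_noise Relative SD of the non-compositional (strain-level)
#'   variation in observed EFPs, as a fraction of the mean EFP value
#'   (default 0.3, under which most of the hidden rule's score variance is
#'   not explainable from genus-level composition).
#' @param flip_noise Probability that an obesity label is flipped
#'   (default 0.05).
#' @param rule_size Number of metabolites in the hidden obesity rule
#'   (default 5).
#' @param vocabulary Taxon vocabulary.
#' @param genomes,offsets,reaction_network Optionally supply an existing
#'   `genome_function_matrix`, true offset matrix and `reaction_network`
#'   instead of generating fresh ones, so the cohort shares its enzyme and
#'   metabolite universe with other simulated datasets.
#' @return An `obesity_cohort` list: `community` (hosts x taxa),
#'   `efp`, `metabolome` (hosts x metabolites PRMT scores), `diet` and
#'   `obesity` (0/1 vectors), and `truth` (hidden rule, genomes, offsets,
#'   reaction network, seed).
#' @export
simulate_obesity_cohort <- function(seed, n_hosts = 54, n_ec = 120,
                                    n_metabolites = 200, mean_degree = 4,
                                    diet_effect = 1.5, efp_noise = 0.3,
                                    flip_noise = 0.05, rule_size = 5,
                                    vocabulary = taxon_vocabulary(),
                                    genomes = NULL, offsets = NULL,
                                    reaction_network = NULL) {
  if (n_hosts < 8) stop("n_hosts must be at least 8 for stratification")
  taxa <- if (is.null(genomes)) vocabulary$name else rownames(genomes$ave)
  k <- length(taxa)
  hosts <- sprintf("host%03d", seq_len(n_hosts))

  diet <- with_seed(sub_seed(seed, "diet_labels"), {
    sample(rep(c(0L, 1L), length.out = n_hosts))
  })

  community <- with_seed(sub_seed(seed, "cohort_communities"), {
    alpha <- stats::rgamma(k, shape = 2, rate = 2) + 0.1
    affected <- sample(k, 6)
    shift <- rep(0, k)
    shift[affected] <- sample(c(-1, 1), 6, replace = TRUE) * diet_effect
    g <- t(vapply(seq_len(n_hosts), function(i) {
      a <- alpha * exp(if (diet[i] == 1) shift else 0)
      stats::rgamma(k, shape = a)
    }, numeric(k)))
    dimnames(g) <- list(hosts, taxa)
    normalize_community(g)
  })

  if (is.null(genomes)) {
    meta <- simulate_metagenome_study(sub_seed(seed, "cohort_meta"),
      n_taxa = k, n_ec = n_ec, n_samples = 2, noise = 0, taxa = taxa)
    genomes <- meta$genomes
    offsets <- meta$offsets
  } else if (is.null(offsets)) {
    offsets <- matrix(0, nrow(genomes$ave), ncol(genomes$ave),
      dimnames = dimnames(genomes$ave))
  }
  efp <- community %*% (genomes$ave + offsets)
  if (efp_noise > 0) {
    efp <- with_seed(sub_seed(seed, "cohort_efp_noise"), {
      efp + matrix(stats::rnorm(length(efp), sd = efp_noise * mean(efp)),
        nrow(efp), ncol(efp))
    })
  }
  efp <- pmax(efp, 0)
  colnames(efp) <- colnames(genomes$ave)

  net <- if (is.null(reaction_network)) {
    simulate_reaction_network(sub_seed(seed, "cohort_net"),
      n_ec = ncol(genomes$ave), n_metabolites = n_metabolites,
      mean_degree = mean_degree)
  } else {
    reaction_network
  }
  metabolome <- compute_prmt(efp, build_connection_matrix(net))

  rule <- with_seed(sub_seed(seed, "rule"), {
    list(
      metabolites = sample(colnames(metabolome), rule_size),
      weights = stats::runif(rule_size, 0.5, 1.5) *
        sample(c(-1, 1), rule_size, replace = TRUE)
    )
  })
  score <- as.numeric(metabolome[, rule$metabolites] %*% rule$weights)
  obesity <- as.integer(score > 0)
  if (flip_noise > 0) {
    flip <- with_seed(sub_seed(seed, "flips"), {
      stats::runif(n_hosts) < flip_noise
    })
    obesity[flip] <- 1L - obesity[flip]
  }
  if (length(unique(obesity)) < 2) {
    obesity[which.min(abs(score))] <- 1L - obesity[which.min(abs(score))]
  }

  structure(
    list(community = community, efp = efp, metabolome = metabolome,
      diet = stats::setNames(diet, hosts),
      obesity = stats::setNames(obesity, hosts),
      truth = list(rule = rule, score = score, genomes = genomes,
        offsets = offsets, reaction_network = net, seed = seed)),
    class = "obesity_cohort"
  )
}
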