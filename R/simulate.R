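#' Simulate a Yule (pure-birth) tree
#'
#' Starts from a root split into two lineages at time zero; with `k`
#' extant lineages the waiting time to the next speciation is exponential
#' with rate `k * birth_rate`, and a uniformly chosen lineage splits. The
#' tree is returned at the moment the `n_tips + 1`-th speciation would
#' occur, so the expected height is `sum(1 / (k * birth_rate))` over
#' `k = 2..n_tips`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0), in events per unit time.
#' @return A binary `phylo` tree with positive branch lengths and tips
#'   labelled `sp001`, `sp002`, ...
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  # node records: children id pair (NULL while the lineage is active/a tip)
  # and the accumulated length of the edge above the node; the root (node 1)
  # splits into nodes 2 and 3 at time zero
  children <- list(c(2L, 3L), NULL, NULL)
  lengths <- c(0, 0, 0)
  active <- c(2L, 3L)
  while (length(active) < n_tips) {
    k <- length(active)
    dt <- rexp(1, k * birth_rate)
    lengths[active] <- lengths[active] + dt
    pick <- active[sample.int(k, 1)]
    ids <- length(children) + c(1L, 2L)
    children[ids] <- list(NULL, NULL)
    lengths[ids] <- 0
    children[[pick]] <- ids
    active <- c(setdiff(active, pick), ids)
  }
  dt <- rexp(1, n_tips * birth_rate)
  lengths[active] <- lengths[active] + dt
  labels <- sprintf("sp%03d", seq_len(n_tips))
  tip_no <- 0L
  emit <- function(id) {
    ch <- children[[id]]
    if (is.null(ch)) {
      tip_no <<- tip_no + 1L
      paste0(labels[tip_no], ":", format(lengths[id], digits = 15))
    } else {
      paste0("(", emit(ch[1]), ",", emit(ch[2]), "):",
             format(lengths[id], digits = 15))
    }
  }
  ch <- children[[1]]
  txt <- paste0("(", emit(ch[1]), ",", emit(ch[2]), ");")
  ape::read.tree(text = txt)
}

#' Simulate a Brownian-motion trait on a tree
#'
#' The root takes value 0 and each branch adds an independent Gaussian
#' increment with variance `sigma2` times the branch length, so tips
#' covary in proportion to shared root-to-ancestor path length.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length, >= 0).
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length), sigma2 >= 0)
  n_tip <- length(tree$tip.label)
  x <- numeric(n_tip + tree$Nnode)
  pre <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  incr <- rnorm(nrow(pre$edge), 0, sqrt(sigma2 * pre$edge.length))
  for (e in seq_len(nrow(pre$edge))) {
    x[pre$edge[e, 2]] <- x[pre$edge[e, 1]] + incr[e]
  }
  setNames(x[seq_len(n_tip)], tree$tip.label)
}

#' Simulate a symmetric Mk (equal-rates) discrete trait on a tree
#'
#' A continuous-time Markov jump process with `n_states` states and total
#' leaving rate `rate` (each of the other states reached at rate
#' `rate / (n_states - 1)`), started from a uniformly drawn root state.
#' Transitions over a branch of length `t` use the closed form
#' `P(same) = 1/L + (1 - 1/L) exp(-rate * L/(L-1) * t)`.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param n_states Number of states (>= 2).
#' @param rate Total transition rate away from the current state (>= 0).
#' @return Named integer vector of tip states in `1..n_states`.
#' @export
simulate_mk_trait <- function(tree, n_states, rate) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            n_states >= 2, rate >= 0)
  n_tip <- length(tree$tip.label)
  L <- n_states
  s <- integer(n_tip + tree$Nnode)
  s[n_tip + 1L] <- sample.int(L, 1)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    par <- s[pre$edge[e, 1]]
    p_same <- 1 / L + (1 - 1 / L) * exp(-rate * L / (L - 1) *
                                          pre$edge.length[e])
    if (runif(1) < p_same) {
      s[pre$edge[e, 2]] <- par
    } else {
      s[pre$edge[e, 2]] <- sample(setdiff(seq_len(L), par), 1)
    }
  }
  setNames(s[seq_len(n_tip)], tree$tip.label)
}

#' Synthetic-dataset configuration
#'
#' Defaults emulate the structure of the real study data: 89 species, 17
#' mixed-type traits with phylogenetic signal, and a response taking one
#' value per receptor subtype (up to 13), driven partly by traits and
#' partly by relatedness. Subtype EC50s sit on a log-spaced grid spanning
#' three orders of magnitude, mirroring the up-to-1,000-fold sensitivity
#' range among species.
#'
#' @param n_tips Number of species.
#' @param birth_rate Yule speciation rate.
#' @param bm_sigma2 Brownian rate for the nine continuous traits (scalar
#'   or per-trait vector).
#' @param mk_rate Mk transition rate for categorical traits (scalar or
#'   per-trait vector over the 3 ordered + 5 nominal traits).
#' @param trait_effects Linear coefficients of the nine continuous traits
#'   on the latent response.
#' @param phylo_weight Fraction of latent-signal variance contributed by
#'   an independent Brownian component on the tree, in `[0, 1]`.
#' @param noise_sd Standard deviation of the residual Gaussian noise on
#'   the latent response (the signal components are standardised).
#' @param n_subtypes Number of receptor subtypes (2-13).
#' @param missing_rate Probability that any one trait cell is missing
#'   (completely at random), in `[0, 1)`.
#' @param n_trees Size of the emitted tree set (the true tree plus
#'   `n_trees - 1` NNI-perturbed replicates for consensus testing).
#' @param nni_moves Nearest-neighbour-interchange moves per replicate.
#' @param ec50_range Range (molar) spanned by the subtype EC50 grid.
#' @param rng_seed Optional seed applied by [simulate_dataset()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tips = 89, birth_rate = 1, bm_sigma2 = 1,
                       mk_rate = 0.5,
                       trait_effects = c(1, 0.5, rep(0, 7)),
                       phylo_weight = 0.3, noise_sd = 0.3, n_subtypes = 13,
                       missing_rate = 0.05, n_trees = 20, nni_moves = 2,
                       ec50_range = c(1e-11, 1e-8), rng_seed = NULL) {
  stopifnot(
    n_tips >= 2, birth_rate > 0,
    phylo_weight >= 0, phylo_weight <= 1,
    noise_sd >= 0, n_subtypes >= 2, n_subtypes <= 13,
    missing_rate >= 0, missing_rate < 1,
    n_trees >= 1, nni_moves >= 0,
    length(ec50_range) == 2, all(ec50_range > 0)
  )
  if (length(trait_effects) != 9) {
    stop("trait_effects must have length 9 (one per continuous trait)",
         call. = FALSE)
  }
  structure(
    list(n_tips = n_tips, birth_rate = birth_rate, bm_sigma2 = bm_sigma2,
         mk_rate = mk_rate, trait_effects = trait_effects,
         phylo_weight = phylo_weight, noise_sd = noise_sd,
         n_subtypes = n_subtypes, missing_rate = missing_rate,
         n_trees = n_trees, nni_moves = nni_moves, ec50_range = ec50_range,
         rng_seed = rng_seed),
    class = "sim_config"
  )
}

#' Simulate a complete synthetic dataset
#'
#' Generates, from one Yule tree: a tree set (the true tree plus
#' NNI-perturbed replicates), a typed 17-trait table with phylogenetic
#' signal and configurable missingness, and a species-to-subtype map with
#' a subtype-to-EC50 grid. The latent response is
#' `sqrt(1 - w) * (standardised trait signal) + sqrt(w) * (standardised
#' Brownian component) + noise`, discretised by quantiles into
#' `n_subtypes` subtypes that are each assigned one EC50 on a log-spaced
#' grid (lower latent value = more sensitive = smaller EC50).
#'
#' @param config A [sim_config()].
#' @return A list with `trees` (`multiPhylo`), `traits` (typed tibble),
#'   `subtypes` (species/subtype tibble), `ec50` (subtype/ec50 tibble),
#'   and `latent` (tibble of the latent response and its components, for
#'   diagnostics and recovery tests).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  schema <- default_trait_schema()
  cont_names <- names(schema)[vapply(schema, function(s)
    s$kind == "continuous", logical(1))]
  cat_names <- setdiff(names(schema), cont_names)

  tree <- simulate_yule_tree(config$n_tips, config$birth_rate)
  reps <- list(tree)
  if (config$n_trees > 1) {
    for (i in seq_len(config$n_trees - 1)) {
      reps[[i + 1]] <- if (config$nni_moves > 0) {
        phangorn::rNNI(tree, moves = config$nni_moves)
      } else {
        tree
      }
    }
  }
  class(reps) <- "multiPhylo"

  species <- tree$tip.label
  n <- length(species)
  sig2 <- rep(config$bm_sigma2, length.out = length(cont_names))
  cont <- lapply(seq_along(cont_names), function(j) {
    unname(simulate_bm_trait(tree, sig2[j])[species])
  })
  names(cont) <- cont_names
  rates <- rep(config$mk_rate, length.out = length(cat_names))
  cats <- lapply(seq_along(cat_names), function(j) {
    sc <- schema[[cat_names[j]]]
    st <- simulate_mk_trait(tree, length(sc$levels), rates[j])[species]
    factor(sc$levels[st], levels = sc$levels,
           ordered = sc$kind == "ordered")
  })
  names(cats) <- cat_names
  traits <- dplyr::bind_cols(tibble::tibble(species = species),
                             tibble::as_tibble(cont),
                             tibble::as_tibble(cats))
  traits <- traits[, c("species", names(schema))]

  # latent response: standardised trait and phylogeny components
  std <- function(x) if (sd(x) > 0) as.numeric(scale(x)) else x * 0
  raw_trait <- as.numeric(do.call(cbind, cont) %*% config$trait_effects)
  trait_comp <- if (any(config$trait_effects != 0)) std(raw_trait)
  else numeric(n)
  phylo_comp <- std(unname(simulate_bm_trait(tree, 1)[species]))
  w <- config$phylo_weight
  latent <- sqrt(1 - w) * trait_comp + sqrt(w) * phylo_comp +
    rnorm(n, 0, config$noise_sd)

  rk <- dplyr::ntile(latent, config$n_subtypes)
  subtype <- sprintf("S%02d", rk)
  ec50_grid <- 10^seq(log10(config$ec50_range[1]),
                      log10(config$ec50_range[2]),
                      length.out = config$n_subtypes)
  ec50 <- tibble::tibble(
    subtype = sprintf("S%02d", seq_len(config$n_subtypes)),
    ec50 = ec50_grid
  )

  if (config$missing_rate > 0) {
    for (nm in names(schema)) {
      drop <- runif(n) < config$missing_rate
      traits[[nm]][drop] <- NA
    }
  }

  list(
    trees = reps,
    traits = traits,
    subtypes = tibble::tibble(species = species, subtype = subtype),
    ec50 = ec50,
    latent = tibble::tibble(species = species, latent = latent,
                            trait_component = trait_comp,
                            phylo_component = phylo_comp)
  )
}

#' Write a simulated dataset in the formats the pipeline consumes
#'
#' @param dataset A list from [simulate_dataset()].
#' @param dir Output directory (created if needed). Writes `trees.nwk`,
#'   `traits.csv`, `schema.yaml`, `subtypes.csv`, `ec50.csv`.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(dataset$trees, file = file.path(dir, "trees.nwk"))
  readr::write_csv(dataset$traits, file.path(dir, "traits.csv"))
  write_trait_schema(default_trait_schema(), file.path(dir, "schema.yaml"))
  readr::write_csv(dataset$subtypes, file.path(dir, "subtypes.csv"))
  readr::write_csv(dataset$ec50, file.path(dir, "ec50.csv"))
  invisible(dir)
}
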