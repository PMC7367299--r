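#' Partition variable importance into trait and phylogeny groups
#'
#' Sums the relative-influence scores within each predictor group. Because
#' VI scores sum to 100, the group totals are the percent of *model*
#' deviance attributed to species traits versus phylogenetic relatedness.
#'
#' @param vi A variable-importance tibble from [variable_importance()]
#'   (columns `term`, `group`, `vi`), or a named numeric vector of VI
#'   scores with `groups` supplied separately.
#' @param groups Optional named character vector mapping each term to its
#'   group; required when `vi` is a bare vector.
#' @return A tibble with `group` and `vi_pct` (summing to 100).
#' @export
partition_vi <- function(vi, groups = NULL) {
  if (!is.data.frame(vi)) {
    if (is.null(groups)) {
      stop("groups must be supplied when vi is a bare vector", call. = FALSE)
    }
    untagged <- setdiff(names(vi), names(groups))
    if (length(untagged) > 0) {
      stop("no group tag for: ", paste(untagged, collapse = ", "),
           call. = FALSE)
    }
    vi <- tibble::tibble(term = names(vi), group = unname(groups[names(vi)]),
                         vi = unname(vi))
  }
  if (anyNA(vi$group)) {
    stop("no group tag for: ",
         paste(vi$term[is.na(vi$group)], collapse = ", "), call. = FALSE)
  }
  out <- dplyr::summarise(dplyr::group_by(vi, .data$group),
                          vi_pct = sum(.data$vi), .groups = "drop")
  # report both groups even when one is absent from the frame
  for (g in c("trait", "phylogeny")) {
    if (all(out$group != g) && any(c("trait", "phylogeny") %in% out$group)) {
      out <- dplyr::bind_rows(out, tibble::tibble(group = g, vi_pct = 0))
    }
  }
  dplyr::arrange(out, dplyr::desc(.data$vi_pct))
}

#' Absolute deviance shares of predictor groups
#'
#' Converts group shares of the *model* deviance into shares of the
#' *response* deviance: each group's absolute share is the total percent
#' deviance explained times the group's fraction of the model deviance.
#' The shares sum to the total by construction.
#'
#' @param total_pct Total percent deviance explained by the model
#'   (`0..100`).
#' @param group_vi_pct Tibble from [partition_vi()] or a named numeric
#'   vector of group percentages summing to 100.
#' @return A tibble with `group`, `vi_pct`, and `abs_pct`.
#' @export
absolute_deviance_shares <- function(total_pct, group_vi_pct) {
  stopifnot(is.numeric(total_pct), length(total_pct) == 1,
            total_pct >= 0, total_pct <= 100)
  if (!is.data.frame(group_vi_pct)) {
    group_vi_pct <- tibble::tibble(group = names(group_vi_pct),
                                   vi_pct = unname(group_vi_pct))
  }
  if (abs(sum(group_vi_pct$vi_pct) - 100) > 1e-6) {
    stop("group VI percentages must sum to 100", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(group_vi_pct),
                abs_pct = total_pct * .data$vi_pct / 100)
}

#' Deviance partition of a fitted BRT
#'
#' Combines the model's percent deviance explained with the trait versus
#' phylogeny split of its variable-importance scores.
#'
#' @param model A fitted `brt`.
#' @param type Deviance type passed to [percent_deviance_explained()].
#' @return An object of class `deviance_partition`: list with `total_pct`
#'   and a `shares` tibble (`group`, `vi_pct`, `abs_pct`).
#' @export
deviance_partition <- function(model,
                               type = if (model$cv) "cv" else "train") {
  total <- percent_deviance_explained(model, type)
  shares <- absolute_deviance_shares(max(0, min(100, total)),
                                     partition_vi(variable_importance(model)))
  structure(list(total_pct = total, shares = shares, type = type),
            class = "deviance_partition")
}

#' @export
print.deviance_partition <- function(x, ...) {
  cat("Deviance partition (", x$type, "): total ",
      sprintf("%.1f%%", x$total_pct), "\n", sep = "")
  for (i in seq_len(nrow(x$shares))) {
    cat(sprintf("  %-10s %5.1f%% of model deviance = %5.1f%% of response\n",
                x$shares$group[i], x$shares$vi_pct[i], x$shares$abs_pct[i]))
  }
  invisible(x)
}

#' @export
tidy.deviance_partition <- function(x, ...) {
  dplyr::mutate(x$shares, total_pct = x$total_pct)
}

#' Pipeline configuration
#'
#' Collects all settings of the end-to-end analysis. Inputs are either
#' file paths (`trees`, `traits`, `schema`, `subtypes`, `ec50`) or, when
#' `sim` is supplied, a synthetic dataset generated on the fly.
#'
#' @param trees,traits,schema,subtypes,ec50 Input file paths (Newick tree
#'   set; trait CSV; YAML column schema; species-to-subtype CSV;
#'   subtype-to-EC50 CSV). Ignored when `sim` is given.
#' @param sim A [sim_config()] for a synthetic run, or `NULL`.
#' @param consensus_threshold Majority-rule clade-frequency cutoff.
#' @param eigen_threshold Cumulative explained-variation threshold for
#'   eigenvector selection.
#' @param response_transform Response transform for [build_response()].
#' @param brt A [brt_config()].
#' @param vi_cutoff Minimum VI score (percent) for the chart data.
#' @param pd_top_n Number of top predictors given partial-dependence
#'   curves.
#' @param interaction_top_n Number of top predictors screened pairwise
#'   for interactions.
#' @param seed Master seed: seeds the simulation and the BRT fit.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(trees = NULL, traits = NULL, schema = NULL,
                            subtypes = NULL, ec50 = NULL, sim = NULL,
                            consensus_threshold = 0.5,
                            eigen_threshold = 0.99,
                            response_transform = "zlog10",
                            brt = brt_config(), vi_cutoff = 0.5,
                            pd_top_n = 6, interaction_top_n = 6, seed = 1) {
  if (is.null(sim) && (is.null(trees) || is.null(traits) ||
                       is.null(subtypes) || is.null(ec50))) {
    stop("either file inputs (trees, traits, subtypes, ec50) or a ",
         "sim config must be supplied", call. = FALSE)
  }
  structure(
    list(trees = trees, traits = traits, schema = schema,
         subtypes = subtypes, ec50 = ec50, sim = sim,
         consensus_threshold = consensus_threshold,
         eigen_threshold = eigen_threshold,
         response_transform = response_transform,
         brt = brt, vi_cutoff = vi_cutoff, pd_top_n = pd_top_n,
         interaction_top_n = interaction_top_n, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes consensus -> patristic distances -> principal coordinates ->
#' eigenvector selection -> model frame -> BRT fit -> variable importance
#' -> deviance partition -> partial dependence and interaction screening,
#' and returns everything as one report object. The run is deterministic
#' given the configuration seed.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `analysis_report`; see [write_report()],
#'   [report_to_json()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  provenance <- list(seed = config$seed)
  if (!is.null(config$sim)) {
    simc <- config$sim
    simc$rng_seed <- simc$rng_seed %||% config$seed
    dataset <- stage("simulate", simulate_dataset(simc))
    trees <- dataset$trees
    traits <- dataset$traits
    subtypes <- dataset$subtypes
    ec50 <- dataset$ec50
    provenance$mode <- "synthetic"
    provenance$sim <- unclass(simc)
  } else {
    trees <- stage("read_trees", read_newick_trees(config$trees))
    schema <- if (is.null(config$schema)) default_trait_schema()
    else stage("read_schema", read_trait_schema(config$schema))
    traits <- stage("read_traits", read_trait_table(config$traits, schema))
    subtypes <- stage("read_subtypes",
                      readr::read_csv(config$subtypes,
                                      show_col_types = FALSE))
    ec50 <- stage("read_ec50",
                  readr::read_csv(config$ec50, show_col_types = FALSE))
    provenance$mode <- "files"
    paths <- c(trees = config$trees, traits = config$traits,
               subtypes = config$subtypes, ec50 = config$ec50)
    provenance$input_md5 <- as.list(tools::md5sum(paths))
  }

  consensus <- stage("consensus",
                     majority_rule_consensus(trees,
                                             config$consensus_threshold))
  distances <- stage("distances", patristic_distance_matrix(consensus))
  basis <- stage("pcoa", phylo_pcoa(distances))
  coords <- stage("select_eigenvectors",
                  select_eigenvectors(basis, config$eigen_threshold))
  response <- stage("response",
                    build_response(subtypes, ec50,
                                   transform = config$response_transform))
  frame <- stage("model_frame", build_model_frame(traits, coords))

  brt_cfg <- config$brt
  brt_cfg$rng_seed <- brt_cfg$rng_seed %||% config$seed
  model <- stage("fit_brt", fit_brt(frame, response, brt_cfg))

  vi <- dplyr::arrange(variable_importance(model), dplyr::desc(.data$vi))
  partition <- deviance_partition(model)
  top_terms <- head(vi$term[vi$improvement > 0], config$pd_top_n)
  pd <- stage("partial_dependence",
              purrr::map_dfr(top_terms, function(tm) {
                # value as character so nominal and continuous terms bind
                dplyr::mutate(partial_dependence(model, frame, tm),
                              value = as.character(.data$value))
              }))
  interactions <- stage("interactions",
                        interaction_table(model, frame,
                                          top_n = config$interaction_top_n))

  structure(
    list(
      partition = partition,
      vi_table = vi,
      chart_data = dplyr::filter(vi, .data$vi >= config$vi_cutoff),
      pd = pd,
      interactions = interactions,
      model = model,
      frame = frame,
      consensus = consensus,
      basis = basis,
      coords = coords,
      response = response,
      config = config,
      provenance = provenance
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  print(x$partition)
  cat("  eigenvectors retained: ", x$coords$k, " (cumulative fraction ",
      format(x$coords$cum_fraction, digits = 4), ")\n", sep = "")
  cat("  top predictors:\n")
  top <- head(x$vi_table, 6)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-24s %5.1f%% (%s)\n", top$term[i], top$vi[i],
                top$group[i]))
  }
  invisible(x)
}

#' Serialise an analysis report to a JSON-ready structure
#'
#' Numbers for presentation are rounded to one decimal (matching the
#' convention for reporting deviance percentages); raw values are kept
#' alongside.
#'
#' @param report An `analysis_report`.
#' @return A named list ready for [jsonlite::write_json()].
#' @export
report_to_json <- function(report) {
  part <- report$partition
  list(
    total_deviance_pct = part$total_pct,
    total_deviance_pct_rounded = round(part$total_pct, 1),
    group_shares = dplyr::mutate(
      part$shares,
      vi_pct_rounded = round(.data$vi_pct, 1),
      abs_pct_rounded = round(.data$abs_pct, 1)
    ),
    n_eigenvectors = report$coords$k,
    eigen_cum_fraction = report$coords$cum_fraction,
    n_trees = report$model$n_trees,
    vi = report$vi_table,
    chart_data = report$chart_data,
    interactions = report$interactions,
    warnings = report$model$warnings %||% character(0),
    provenance = report$provenance
  )
}

#' Write an analysis report to disk
#'
#' Writes `report.json`, `vi.csv`, `partial_dependence.csv`,
#' `interactions.csv`, `consensus.nwk` and `eigenvectors.csv` under `dir`.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_json(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_csv(report$vi_table, file.path(dir, "vi.csv"))
  pd_out <- dplyr::mutate(report$pd, value = as.character(.data$value))
  readr::write_csv(pd_out, file.path(dir, "partial_dependence.csv"))
  readr::write_csv(report$interactions, file.path(dir, "interactions.csv"))
  ape::write.tree(report$consensus, file.path(dir, "consensus.nwk"))
  readr::write_csv(report$coords$scores, file.path(dir, "eigenvectors.csv"))
  invisible(dir)
}
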