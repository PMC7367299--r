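#' Default 17-trait schema for the avian sensitivity analysis
#'
#' Declares the column kinds and category levels of the species-trait table:
#' nine continuous traits (incubation period \[days\], fledge period
#' \[days\], clutch size \[eggs\], broods per year, body mass \[g\], percent
#' of female body mass represented by the clutch, migration distance
#' \[degrees latitude\], lifespan \[years\], residual testes mass), three
#' ordered categoricals (breeding range 1-5 and wintering range 1-5 from
#' very widespread to highly restricted; breeding coloniality 0 = solitary,
#' 1 = semi-colonial, 2 = colonial) and five unordered categoricals (stage
#' at hatch, migration route, social mating system, habitat, foraging
#' guild).
#'
#' @return A named list; each element has `kind` (`"continuous"`,
#'   `"ordered"` or `"nominal"`) and, for categoricals, `levels`.
#' @export
default_trait_schema <- function() {
  cont <- function() list(kind = "continuous")
  ord <- function(levels) list(kind = "ordered", levels = levels)
  nom <- function(levels) list(kind = "nominal", levels = levels)
  list(
    incubation_period = cont(),
    fledge_period = cont(),
    stage_at_hatch = nom(c("precocial", "altricial")),
    clutch_size = cont(),
    broods_per_year = cont(),
    body_mass = cont(),
    clutch_mass_pct = cont(),
    migration_route = nom(c("non-migratory", "continental", "coastal",
                            "continental_and_coastal", "coastal_and_oceanic",
                            "all_routes")),
    migration_distance = cont(),
    breeding_range = ord(as.character(1:5)),
    wintering_range = ord(as.character(1:5)),
    testes_mass_residual = cont(),
    mating_system = nom(c("polyandrous", "monogamous", "mostly_monogamous",
                          "polygynous", "lekking_promiscuous",
                          "cooperative_breeder")),
    breeding_coloniality = ord(as.character(0:2)),
    habitat = nom(c("urban", "forest", "grassland", "lake_pond", "marsh",
                    "mountain", "ocean", "open_woodland", "scrub",
                    "shoreline")),
    foraging_guild = nom(c("carnivorous", "herbivorous", "insectivorous",
                           "invertivorous", "omnivorous", "piscivorous")),
    lifespan = cont()
  )
}

#' Read or write a trait-column schema as YAML
#'
#' @param path YAML file path.
#' @return For `read_trait_schema`, the schema list; for
#'   `write_trait_schema`, `path` invisibly.
#' @export
read_trait_schema <- function(path) {
  schema <- yaml::read_yaml(path)
  for (nm in names(schema)) {
    kind <- schema[[nm]]$kind
    if (is.null(kind) || !kind %in% c("continuous", "ordered", "nominal")) {
      stop("column '", nm, "' has invalid kind: ", kind %||% "<missing>",
           call. = FALSE)
    }
    if (kind != "continuous" && is.null(schema[[nm]]$levels)) {
      stop("categorical column '", nm, "' declares no levels", call. = FALSE)
    }
  }
  schema
}

#' @rdname read_trait_schema
#' @param schema A schema list as returned by [default_trait_schema()].
#' @export
write_trait_schema <- function(schema, path) {
  yaml::write_yaml(schema, path)
  invisible(path)
}

#' Read a typed species-trait table
#'
#' Reads a CSV with a `species` column and one column per trait, applying
#' the declared kinds: continuous columns become doubles, ordered
#' categoricals become ordered factors over the declared level order, and
#' unordered categoricals become plain factors. Missing cells are allowed
#' anywhere; values outside the declared levels are an error.
#'
#' @param path Trait CSV path.
#' @param schema Column schema (default [default_trait_schema()]).
#' @return A tibble with unique `species` plus typed trait columns.
#' @export
read_trait_table <- function(path, schema = default_trait_schema()) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!"species" %in% names(raw)) {
    stop("trait table must have a 'species' column", call. = FALSE)
  }
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0) {
    stop("trait table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(species = raw$species)
  if (anyDuplicated(out$species)) {
    stop("duplicate species labels in trait table", call. = FALSE)
  }
  for (nm in names(schema)) {
    x <- raw[[nm]]
    kind <- schema[[nm]]$kind
    if (kind == "continuous") {
      out[[nm]] <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & is.na(out[[nm]])
      if (any(bad)) {
        stop("non-numeric value in continuous column '", nm, "': ",
             x[which(bad)[1]], call. = FALSE)
      }
    } else {
      levels <- as.character(schema[[nm]]$levels)
      bad <- !is.na(x) & !x %in% levels
      if (any(bad)) {
        stop("value outside declared levels in '", nm, "': ",
             x[which(bad)[1]], call. = FALSE)
      }
      out[[nm]] <- factor(x, levels = levels, ordered = kind == "ordered")
    }
  }
  out
}

#' Residual testes mass
#'
#' Corrects testes mass for body size as the ordinary least-squares
#' residuals of a regression of testes mass on body mass, computed over
#' complete cases. Both masses are log10-transformed by default (the
#' allometric convention); species missing either input receive a missing
#' residual.
#'
#' @param testes_mass Per-species testes mass in grams (positive).
#' @param body_mass Per-species body mass in grams (positive).
#' @param log10_scale Regress on the log10 scale (default) or raw scale.
#' @return Numeric vector of residuals, `NA` where either input is missing.
#' @export
residual_testes_mass <- function(testes_mass, body_mass, log10_scale = TRUE) {
  if (length(testes_mass) != length(body_mass)) {
    stop("testes_mass and body_mass must have equal length", call. = FALSE)
  }
  if (any(testes_mass <= 0, na.rm = TRUE) || any(body_mass <= 0, na.rm = TRUE)) {
    stop("masses must be positive", call. = FALSE)
  }
  complete <- !is.na(testes_mass) & !is.na(body_mass)
  if (sum(complete) < 3) {
    stop("need at least 3 complete cases to fit the regression",
         call. = FALSE)
  }
  x <- if (log10_scale) log10(body_mass) else body_mass
  y <- if (log10_scale) log10(testes_mass) else testes_mass
  fit <- lm(y ~ x, subset = complete)
  out <- rep(NA_real_, length(y))
  out[complete] <- y[complete] - unname(predict(fit, list(x = x[complete])))
  out
}

#' Migration distance in degrees latitude
#'
#' The absolute difference between the latitudinal midpoints of a species'
#' breeding and wintering ranges. Each argument is either a vector of
#' midpoints or a two-column matrix/data frame of north/south range
#' extents, in which case the midpoint is the median (mean) of the two
#' extents.
#'
#' @param breeding,wintering Midpoint latitudes in degrees, or two-column
#'   extents; all values must lie in `[-90, 90]`.
#' @return Nonnegative migration distances in degrees latitude.
#' @export
migration_distance <- function(breeding, wintering) {
  mid <- function(x) {
    if (is.matrix(x) || is.data.frame(x)) {
      x <- as.matrix(x)
      if (ncol(x) != 2) stop("range extents need two columns", call. = FALSE)
      rowMeans(x)
    } else {
      as.numeric(x)
    }
  }
  check <- function(x, what) {
    if (any(abs(x) > 90, na.rm = TRUE)) {
      stop(what, " latitude outside [-90, 90]", call. = FALSE)
    }
    x
  }
  b <- check(if (is.matrix(breeding) || is.data.frame(breeding))
    as.matrix(breeding) else breeding, "breeding")
  w <- check(if (is.matrix(wintering) || is.data.frame(wintering))
    as.matrix(wintering) else wintering, "wintering")
  abs(mid(b) - mid(w))
}

#' Build the continuous sensitivity response from subtype EC50 values
#'
#' Maps each species to the in vitro EC50 of its receptor subtype and
#' transforms the EC50s into a dimensionless response. The default
#' transform is the z-score of log10 EC50 across species; because every
#' species of a subtype shares one EC50, the response takes at most as many
#' distinct values as there are subtypes, and larger EC50 (lower
#' sensitivity) always maps to a larger response.
#'
#' @param subtype_by_species Data frame with columns `species` and
#'   `subtype`, or a named character vector (names = species).
#' @param ec50_by_subtype Data frame with columns `subtype` and `ec50`
#'   (positive, molar scale), or a named numeric vector.
#' @param transform `"zlog10"` (default), `"log10"`, or `"raw"`.
#' @return A tibble with `species`, `subtype`, `ec50`, `response`.
#' @export
build_response <- function(subtype_by_species, ec50_by_subtype,
                           transform = c("zlog10", "log10", "raw")) {
  transform <- match.arg(transform)
  if (!is.data.frame(subtype_by_species)) {
    subtype_by_species <- tibble::tibble(
      species = names(subtype_by_species),
      subtype = unname(as.character(subtype_by_species))
    )
  }
  if (!is.data.frame(ec50_by_subtype)) {
    ec50_by_subtype <- tibble::tibble(
      subtype = names(ec50_by_subtype),
      ec50 = unname(as.numeric(ec50_by_subtype))
    )
  }
  missing_st <- setdiff(unique(subtype_by_species$subtype),
                        ec50_by_subtype$subtype)
  if (length(missing_st) > 0) {
    stop("no EC50 for subtype(s): ", paste(missing_st, collapse = ", "),
         call. = FALSE)
  }
  if (any(ec50_by_subtype$ec50 <= 0)) {
    stop("EC50 values must be positive", call. = FALSE)
  }
  out <- dplyr::left_join(
    tibble::as_tibble(subtype_by_species),
    tibble::as_tibble(ec50_by_subtype),
    by = "subtype"
  )
  lg <- log10(out$ec50)
  out$response <- switch(
    transform,
    raw = out$ec50,
    log10 = lg,
    zlog10 = {
      if (sd(lg) == 0) {
        stop("response is degenerate: all species share one subtype/EC50",
             call. = FALSE)
      }
      as.numeric(scale(lg))
    }
  )
  attr(out, "transform") <- transform
  out
}

#' Assemble the predictor frame of traits plus phylogenetic eigenvectors
#'
#' Aligns the trait table with the selected eigenvector scores by species
#' label and concatenates them into one predictor frame. Trait columns are
#' tagged `trait` and eigenvector columns `phylogeny`; ordered categoricals
#' are carried as integer ranks and unordered categoricals as level codes
#' (no dummy expansion — the tree learner consumes levels directly).
#' Missing values may occur only in trait columns.
#'
#' @param traits Typed trait tibble with a `species` column (see
#'   [read_trait_table()]).
#' @param coords A `phylo_coords` object, its `scores` tibble, or `NULL`
#'   for a trait-only frame.
#' @return An object of class `model_frame`: list with `species`, `data`
#'   (tibble of predictors), `kind` and `group` per column.
#' @export
build_model_frame <- function(traits, coords = NULL) {
  stopifnot(is.data.frame(traits), "species" %in% names(traits))
  traits <- tibble::as_tibble(traits)
  ev <- NULL
  if (!is.null(coords)) {
    ev <- if (inherits(coords, "phylo_coords")) coords$scores else
      tibble::as_tibble(coords)
    if (ncol(ev) <= 1) ev <- NULL
  }
  if (!is.null(ev)) {
    only_traits <- setdiff(traits$species, ev$species)
    only_coords <- setdiff(ev$species, traits$species)
    if (length(only_traits) > 0 || length(only_coords) > 0) {
      stop("species mismatch between traits and coordinates; ",
           "only in traits: [", paste(only_traits, collapse = ", "),
           "], only in coordinates: [",
           paste(only_coords, collapse = ", "), "]", call. = FALSE)
    }
    ev <- ev[match(traits$species, ev$species), ]
    if (anyNA(ev)) {
      stop("eigenvector scores contain missing values", call. = FALSE)
    }
  }
  trait_cols <- traits[setdiff(names(traits), "species")]
  kind <- vapply(trait_cols, function(x) {
    if (is.ordered(x)) "ordered"
    else if (is.factor(x) || is.character(x)) "nominal"
    else "continuous"
  }, character(1))
  trait_cols <- dplyr::mutate(
    trait_cols,
    dplyr::across(dplyr::where(is.character), ~ factor(.x))
  )
  data <- trait_cols
  group <- rep("trait", ncol(trait_cols))
  if (!is.null(ev)) {
    ev_cols <- ev[setdiff(names(ev), "species")]
    data <- dplyr::bind_cols(data, ev_cols)
    kind <- c(kind, rep("continuous", ncol(ev_cols)))
    group <- c(group, rep("phylogeny", ncol(ev_cols)))
  }
  names(kind) <- names(data)
  names(group) <- names(data)
  structure(
    list(species = traits$species, data = data, kind = kind, group = group),
    class = "model_frame"
  )
}

#' @export
print.model_frame <- function(x, ...) {
  cat("<model_frame> ", length(x$species), " species x ", ncol(x$data),
      " predictors (", sum(x$group == "trait"), " trait, ",
      sum(x$group == "phylogeny"), " phylogeny)\n", sep = "")
  invisible(x)
}

# Encode a model_frame as the numeric matrix the tree engine consumes:
# continuous as-is, ordered as integer ranks, nominal as 1-based level codes
# with kind flag 1. Returns matrix, integer kind vector and level tables.
encode_model_frame <- function(frame) {
  stopifnot(inherits(frame, "model_frame"))
  cols <- lapply(names(frame$data), function(nm) {
    x <- frame$data[[nm]]
    if (frame$kind[[nm]] == "nominal") as.numeric(as.integer(x))
    else if (is.factor(x)) as.numeric(as.integer(x))
    else as.numeric(x)
  })
  x <- do.call(cbind, cols)
  colnames(x) <- names(frame$data)
  levels <- lapply(frame$data, function(col) {
    if (is.factor(col)) levels(col) else NULL
  })
  list(
    x = x,
    kind_int = as.integer(frame$kind == "nominal"),
    levels = levels
  )
}
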