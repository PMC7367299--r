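# Small in-code fixtures shared across tests.

# A model frame of purely continuous predictors from a plain matrix.
continuous_frame <- function(x) {
  colnames(x) <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  df <- tibble::as_tibble(as.data.frame(x))
  df <- dplyr::bind_cols(
    tibble::tibble(species = sprintf("s%03d", seq_len(nrow(x)))), df
  )
  build_model_frame(df, NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a multiPhylo (or list of newick strings) to a temp file.
newick_file <- function(trees) {
  tf <- tempfile(fileext = ".nwk")
  if (is.character(trees)) {
    writeLines(trees, tf)
  } else {
    ape::write.tree(trees, file = tf)
  }
  tf
}

# A tiny typed trait table for n species covering all three column kinds.
tiny_traits <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    species = sprintf("s%03d", seq_len(n)),
    mass = rlnorm(n, 2, 1),
    span = rnorm(n, 10, 2),
    colony = factor(sample(as.character(0:2), n, replace = TRUE),
                    levels = as.character(0:2), ordered = TRUE),
    guild = factor(sample(c("a", "b", "c"), n, replace = TRUE),
                   levels = c("a", "b", "c"))
  )
}
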