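test_that("residual testes mass is the log-log OLS residual", {
  # testes exactly proportional to body mass on the log scale
  body <- c(10, 100, 1000, 5000)
  testes <- 0.01 * body
  expect_equal(residual_testes_mass(testes, body), rep(0, 4),
               tolerance = 1e-12)

  # hand-computed OLS on 3 points
  body <- c(10, 100, 1000)
  testes <- c(0.2, 1.5, 40)
  x <- log10(body); y <- log10(testes)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(residual_testes_mass(testes, body), y - alpha - beta * x,
               tolerance = 1e-10)

  # residuals sum to zero over complete cases; missing stays missing
  set.seed(1)
  body <- rlnorm(20, 5, 1)
  testes <- 0.01 * body^0.9 * rlnorm(20, 0, 0.3)
  testes[c(3, 7)] <- NA
  r <- residual_testes_mass(testes, body)
  expect_true(all(is.na(r[c(3, 7)])))
  expect_equal(sum(r, na.rm = TRUE), 0, tolerance = 1e-9)

  expect_error(residual_testes_mass(c(1, 2), c(1, 2)), "3 complete cases")
  expect_error(residual_testes_mass(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("migration distance handles midpoints and range extents", {
  expect_equal(migration_distance(55, 15), 40)
  expect_equal(migration_distance(23.5, 23.5), 0)
  expect_equal(
    migration_distance(cbind(40, 60), cbind(0, 20)), 40
  )
  expect_equal(migration_distance(c(55, 10), c(15, -10)), c(40, 20))
  expect_error(migration_distance(95, 10), "latitude")
})

test_that("response construction is monotone, tied by subtype, and
           scale-invariant", {
  st <- tibble::tibble(species = paste0("s", 1:6),
                       subtype = c("A", "A", "B", "B", "C", "C"))
  ec <- tibble::tibble(subtype = c("A", "B", "C"),
                       ec50 = c(1e-10, 1e-9, 1e-8))
  r <- build_response(st, ec)
  expect_equal(length(unique(r$response)), 3)
  expect_true(all(diff(r$response[c(1, 3, 5)]) > 0))
  expect_equal(mean(r$response), 0, tolerance = 1e-12)
  expect_equal(sd(r$response), 1, tolerance = 1e-12)
  # same subtype => identical response
  expect_equal(r$response[1], r$response[2])
  # EC50 unit rescaling leaves the z-scored response unchanged
  ec2 <- dplyr::mutate(ec, ec50 = ec50 * 1000)
  expect_equal(build_response(st, ec2)$response, r$response,
               tolerance = 1e-12)
  # two subtypes with an EC50 ratio of 100: log10 gap of 2, z-scored
  st2 <- tibble::tibble(species = c("a", "b"), subtype = c("A", "B"))
  ec3 <- tibble::tibble(subtype = c("A", "B"), ec50 = c(1e-9, 1e-7))
  r2 <- build_response(st2, ec3)
  expect_equal(diff(r2$response), 2 / sd(c(0, 2)))

  expect_error(
    build_response(tibble::tibble(species = c("a", "b"),
                                  subtype = c("A", "A")), ec),
    "degenerate"
  )
  expect_error(
    build_response(st, ec[1:2, ]),
    "no EC50"
  )
})

test_that("trait tables read with declared types and reject bad levels", {
  traits <- tiny_traits(8)
  schema <- list(
    mass = list(kind = "continuous"),
    span = list(kind = "continuous"),
    colony = list(kind = "ordered", levels = as.character(0:2)),
    guild = list(kind = "nominal", levels = c("a", "b", "c"))
  )
  tf <- tempfile(fileext = ".csv")
  readr::write_csv(traits, tf)
  got <- read_trait_table(tf, schema)
  expect_true(is.ordered(got$colony))
  expect_false(is.ordered(got$guild))
  expect_true(is.factor(got$guild))
  expect_type(got$mass, "double")

  # schema YAML round trip
  yf <- tempfile(fileext = ".yaml")
  write_trait_schema(schema, yf)
  expect_equal(read_trait_schema(yf), schema)

  bad <- traits
  bad$guild <- as.character(bad$guild)
  bad$guild[1] <- "z"
  readr::write_csv(bad, tf)
  expect_error(read_trait_table(tf, schema), "outside declared levels")
})

test_that("the default schema declares the 17 study traits", {
  schema <- default_trait_schema()
  expect_length(schema, 17)
  kinds <- vapply(schema, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "continuous"), 9)
  expect_equal(sum(kinds == "ordered"), 3)
  expect_equal(sum(kinds == "nominal"), 5)
  expect_length(schema$habitat$levels, 10)
  expect_length(schema$migration_route$levels, 6)
  expect_equal(schema$breeding_range$levels, as.character(1:5))
})

test_that("model frame concatenates traits and eigenvectors with tags", {
  traits <- tiny_traits(10)
  coords <- tibble::tibble(species = traits$species,
                           EV1 = rnorm(10), EV2 = rnorm(10))
  frame <- build_model_frame(traits, coords)
  expect_equal(ncol(frame$data), 4 + 2)
  expect_equal(unname(frame$group),
               c(rep("trait", 4), rep("phylogeny", 2)))
  expect_equal(unname(frame$kind[c("colony", "guild", "EV1")]),
               c("ordered", "nominal", "continuous"))
  # ordered categoricals stay single integer-rank columns
  enc <- phylobrt:::encode_model_frame(frame)
  expect_equal(sort(unique(enc$x[, "colony"])),
               sort(unique(as.integer(traits$colony))))

  # trait-only frame
  f0 <- build_model_frame(traits, NULL)
  expect_equal(ncol(f0$data), 4)

  # label-driven alignment: permuting input rows matches identically
  perm <- sample(nrow(coords))
  frame2 <- build_model_frame(traits, coords[perm, ])
  expect_equal(frame$data, frame2$data)

  # mismatch lists the offenders
  expect_error(
    build_model_frame(traits, dplyr::mutate(coords, species = c(
      species[-1], "zebra"
    ))),
    "zebra"
  )
})
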