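test_that("default schema has the documented shape", {
  sc <- default_schema()
  expect_equal(nrow(sc), 17)
  expect_false(anyDuplicated(sc$name) > 0)
  expect_equal(as.integer(table(sc$dimension)[c("sociodemographic",
                                                "psychopathology",
                                                "personality")]),
               c(4L, 6L, 7L))
  expect_true(all(!is.na(sc$positive_level[sc$mtype == "binary"])))
  expect_error(variable_schema(sc[-1, ] |>
                                 dplyr::mutate(positive_level =
                                   ifelse(mtype == "binary", NA, positive_level))),
               "positive_level")
})

test_that("well-formed CSV round-trips through the loader", {
  co <- make_toy_cohort(seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- load_cohort(path)
  expect_equal(tibble::as_tibble(co2), tibble::as_tibble(co))
  expect_equal(nrow(co2), 70)
})

test_that("loader rejects malformed tables with named diagnostics", {
  co <- make_toy_cohort(seed = 5)
  df <- tibble::as_tibble(co)

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df[setdiff(names(df), "TCI.directed")], path)
  expect_error(load_cohort(path), "TCI.directed")

  df_bad <- df
  df_bad$Age[3] <- NA
  readr::write_csv(df_bad, path, na = "")
  expect_error(load_cohort(path), "row")
  expect_equal(nrow(load_cohort(path, listwise_deletion = TRUE)),
               nrow(df) - 1)

  df_bad <- df
  df_bad$Age[5] <- "forty"
  readr::write_csv(df_bad, path)
  expect_error(load_cohort(path), "non-numeric.*Age.*5")

  df_bad <- df
  df_bad$Sex.Male[2] <- 2
  readr::write_csv(df_bad, path)
  expect_error(load_cohort(path), "Sex.Male")
})

test_that("stratum split partitions rows and flags unstable sizes", {
  co <- generate_cohort(default_design(), seed = 2)
  parts <- split_by_stratum(co)
  expect_equal(nrow(parts$positive), 78)
  expect_equal(nrow(parts$negative), 131)
  expect_equal(nrow(parts$positive) + nrow(parts$negative), 209)

  # row multiset preserved
  recombined <- dplyr::bind_rows(tibble::as_tibble(parts$positive),
                                 tibble::as_tibble(parts$negative))
  expect_equal(dplyr::arrange(recombined, dplyr::across(dplyr::everything())),
               dplyr::arrange(tibble::as_tibble(co),
                              dplyr::across(dplyr::everything())))

  all_neg <- tibble::as_tibble(co) |> dplyr::mutate(FA = 0)
  expect_error(split_by_stratum(as_cohort(all_neg)), "empty")

  small <- make_toy_cohort(n_positive = 20, n_negative = 20, seed = 6)
  expect_no_warning(split_by_stratum(small))
  smaller <- make_toy_cohort(n_positive = 20, n_negative = 21, seed = 6)
  smaller <- as_cohort(dplyr::slice(tibble::as_tibble(smaller), -1))
  expect_warning(split_by_stratum(smaller), "fewer than 20")
})

test_that("GEXF and GraphML files round-trip graphs exactly", {
  g <- random_test_graph(17, p_edge = 0.4, seed = 11, signed = TRUE)
  for (fmt in c("gexf", "graphml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_graph_file(g, path, fmt)
    g2 <- read_graph_file(path)
    expect_equal(g2$nodes$name, g$nodes$name)
    key <- function(gr) paste(gr$edges$from, gr$edges$to)
    expect_setequal(key(g2), key(g))
    expect_equal(g2$edges$weight[match(key(g), key(g2))], g$edges$weight,
                 tolerance = 1e-12)
    # negative weights preserved with sign
    expect_true(any(g2$edges$weight < 0))
  }
})

test_that("an edgeless graph serializes to a valid zero-edge file", {
  g <- weighted_graph(tibble::tibble(name = c("a", "b", "c")))
  path <- withr::local_tempfile(fileext = ".gexf")
  write_graph_file(g, path, "gexf")
  g2 <- read_graph_file(path)
  expect_equal(nrow(g2$edges), 0)
  expect_equal(g2$nodes$name, c("a", "b", "c"))
  expect_error(write_graph_file(g, path, "dot"), "arg")
})

test_that("GraphML output is readable by an independent parser", {
  g <- random_test_graph(10, p_edge = 0.4, seed = 3)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graph_file(g, path, "graphml")
  ig <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(ig), 10)
  expect_equal(igraph::ecount(ig), nrow(g$edges))
  expect_equal(sort(igraph::E(ig)$weight), sort(g$edges$weight),
               tolerance = 1e-12)
})

test_that("reports round-trip through JSON bit-for-bit", {
  co <- generate_cohort(default_design(), seed = 3)
  rep <- network_report(split_by_stratum(co)$positive, "FA+", seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  rep2 <- read_report(path)
  expect_identical(rep2$global_metrics$density, rep$global_metrics$density)
  expect_identical(rep2$global_metrics$avg_path_length,
                   rep$global_metrics$avg_path_length)
  expect_identical(rep2$centrality$eigenvector, rep$centrality$eigenvector)
  expect_identical(rep2$graph$edges$weight, rep$graph$edges$weight)
  expect_identical(rep2$communities$modularity, rep$communities$modularity)

  # a two-strata bundle becomes a JSON array of length 2
  write_report(list(rep, rep), path)
  expect_length(jsonlite::read_json(path), 2)
  expect_length(read_report(path), 2)
})
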