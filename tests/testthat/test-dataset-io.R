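test_that("table loading applies the SMILES length and row limits", {
  tmp <- withr::local_tempdir()
  smiles <- c(rep("*CC(CC)*", 9), paste0("*", strrep("C", 88), "*")) # one 90-char row
  csv <- file.path(tmp, "in.csv")
  readr::write_csv(tibble::tibble(SMILES = smiles, `Tg (C)` = seq(-50, 40, 10)), csv)

  tbl <- load_polymer_table(csv, max_len = 85)
  expect_equal(nrow(tbl), 9L)
  expect_true("tg_c" %in% names(tbl))
  expect_equal(tbl$tg_c, seq(-50, 30, 10))

  txt <- file.path(tmp, "in.txt")
  writeLines(c("*CC*", "*CCC*", "*CCCC*"), txt)
  expect_equal(nrow(load_polymer_table(txt, max_rows = 2)), 2L)

  expect_error(load_polymer_table(csv, smiles_col = "nope"), "not found")
  expect_error(load_polymer_table(file.path(tmp, "ghost.csv")), "no such file")
})

test_that("batch conversion conserves records and reports outcomes", {
  smiles <- c("*CC(CC)*", "*CC(COC)O*", "*OCCOC(=O)CCCCC(=O)*",
              "CCO", "*CC(*)C*", "*CC)C*")
  out <- convert_polymers(smiles, roundtrip = TRUE)
  g <- generics::glance(out)
  expect_equal(g$n_input, 6L)
  expect_equal(g$n_converted + g$n_rejected, g$n_input)
  expect_equal(g$n_converted, 3L)
  expect_equal(g$n_roundtrip_pass, 3L)
  td <- generics::tidy(out)
  expect_equal(sum(td$n), 6L)
  p <- ggplot2::autoplot(out)
  expect_s3_class(p, "ggplot")
})

test_that("chunked writing uses offset nomenclature and reads back exactly", {
  tmp <- withr::local_tempdir()
  n <- 250L
  data <- tibble::tibble(
    smiles = rep("*CC(CC)*", n),
    bigsmiles = rep("{$CC(CC)$}", n),
    variant = "AA", status = "converted",
    reason = NA_character_, rotation_used = NA_integer_,
    core = "CC(CC)", row = seq_len(n)
  )
  files <- write_conversion_chunks(data, tmp, chunk_size = 100L, stem = "poly")
  expect_equal(basename(files$file), c("poly_0.csv", "poly_100.csv", "poly_200.csv"))
  expect_equal(files$n, c(100L, 100L, 50L))
  back <- dplyr::bind_rows(lapply(files$file, readr::read_csv, show_col_types = FALSE))
  expect_equal(back$row, data$row)
  expect_equal(back$bigsmiles, data$bigsmiles)

  # rejected rows stay out of the files (they live in the report)
  data$status[1:10] <- "rejected"
  files2 <- write_conversion_chunks(data, file.path(tmp, "b"), chunk_size = 100L)
  expect_equal(sum(files2$n), 240L)
})

test_that("a 966-record table lands in a single chunk file", {
  tmp <- withr::local_tempdir()
  data <- tibble::tibble(smiles = rep("x", 966), status = "converted")
  files <- write_conversion_chunks(data, tmp, chunk_size = 100000L)
  expect_equal(nrow(files), 1L)
  expect_equal(files$n, 966L)
})
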