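test_that("bundled dataset loads with all printed descriptor and response cells", {
  tab <- bundled_paper_dataset()
  expect_s3_class(tab, "compound_table")
  expect_equal(nrow(tab$compounds), 19L)
  expect_equal(nrow(tab$retention), 76L)

  cmp <- tab$compounds
  r6 <- cmp[cmp$compound_id == "6", ]
  expect_equal(r6$mw, 325.19)
  expect_equal(r6$tpsa, 48.27)
  expect_equal(r6$substituent, "3,4-Cl2")
  expect_equal(cmp$log_Kp[cmp$compound_id == "10"], -6.245)

  des <- tab$descriptors
  expect_equal(des$log_kw_iam[des$compound_id == "15"], 0.48)
  expect_equal(des$log_kw_ods[des$compound_id == "15"], 1.21)
  k15 <- tab$retention[tab$retention$compound_id == "1" &
                         tab$retention$x == 0.15, ]
  expect_equal(k15$k, 10.53)
  # log_k01 derived from the 0.1 M micellar column
  expect_equal(des$log_k01[des$compound_id == "1"], log10(12.03))

  # normalized decimal-comma rows carry the same TPSA as the rest of series C
  expect_equal(cmp$tpsa[cmp$series == "C"], rep(74.57, 5))
})

test_that("bundled fixture column checksums cover every printed cell once", {
  tab <- bundled_paper_dataset()
  cmp <- tab$compounds
  # per-column sums over the 19 records, frozen from the transcribed tables
  expect_equal(sum(cmp$mw), 5795.4, tolerance = 1e-8)
  expect_equal(sum(cmp$tpsa), 1057.86, tolerance = 1e-8)
  expect_equal(sum(cmp$alpha), 568.85, tolerance = 1e-8)
  expect_equal(sum(cmp$log_p), 40.89, tolerance = 1e-8)
  expect_equal(sum(cmp$log_Kp), -113.739, tolerance = 1e-8)
  expect_equal(sum(cmp$log_KaHSA), 98.31, tolerance = 1e-8)
  expect_equal(sum(cmp$log_BB), 3.401, tolerance = 1e-8)
  expect_equal(sum(cmp$caco2_e06), 3857)
  expect_equal(sum(cmp$fu_brain), 7.29, tolerance = 1e-8)
  expect_equal(sum(tab$retention$k), 1345.05, tolerance = 1e-8)
  des <- tab$descriptors
  expect_equal(sum(des$log_km), 30.48, tolerance = 1e-8)
  expect_equal(sum(des$foley_r_squared), 18.0467, tolerance = 1e-8)
  expect_equal(sum(des$log_kw_iam), 25.66, tolerance = 1e-8)
  expect_equal(sum(des$log_kw_ods), 41.38, tolerance = 1e-8)
})

test_that("file round trip is lossless and unicode labels survive", {
  tab <- bundled_paper_dataset()
  tab$compounds$substituent[1] <- "3,4-Cl₂ (α-substituted)"
  paths <- file.path(tempdir(), c("c.csv", "r.csv", "d.csv"))
  write_compound_table(tab, paths[1], retention = paths[2],
                       descriptors = paths[3])
  back <- read_compound_table(paths[1], retention = paths[2],
                              descriptors = paths[3])
  expect_equal(back$compounds, tab$compounds)
  expect_equal(back$retention, tab$retention)
  expect_equal(back$descriptors, tab$descriptors)
  unlink(paths)
})

test_that("header-only files, tiny tables and delimiters are handled", {
  p <- tempfile(fileext = ".csv")
  writeLines("compound_id,mw,tpsa,alpha", p)
  empty <- read_compound_table(p)
  expect_equal(nrow(empty$compounds), 0L)

  one <- compound_table(tibble::tibble(compound_id = "x", mw = 300,
                                       tpsa = 50, alpha = 30))
  write_compound_table(one, p)
  expect_length(readLines(p), 2L)

  # tab-delimited files are auto-detected
  pt <- tempfile(fileext = ".tsv")
  readr::write_tsv(one$compounds, pt)
  expect_equal(read_compound_table(pt)$compounds$mw, 300)
  unlink(c(p, pt))
})

test_that("schema and invariant violations raise typed errors", {
  base <- tibble::tibble(compound_id = c("a", "b"), mw = c(300, 310),
                         tpsa = c(50, 60), alpha = c(30, 31))
  expect_error(compound_table(base[-2]), class = "mlcqsar_schema_error",
               regexp = "mw")
  dup <- base; dup$compound_id <- c("a", "a")
  expect_error(compound_table(dup), class = "mlcqsar_validation_error",
               regexp = "duplicated")
  bad_fu <- base; bad_fu$fu_brain <- c(0.5, 1.4)
  expect_error(compound_table(bad_fu), class = "mlcqsar_validation_error",
               regexp = "fu_brain")
  ret <- tibble::tibble(compound_id = "a", system = "MLC",
                        x_kind = "surfactant_molarity", x = 0.1, k = -2)
  expect_error(compound_table(base, ret), class = "mlcqsar_validation_error",
               regexp = "compound 'a'")
  orphan <- tibble::tibble(compound_id = "zzz", system = "MLC",
                           x_kind = "surfactant_molarity", x = 0.1, k = 2)
  expect_error(compound_table(base, orphan),
               class = "mlcqsar_validation_error", regexp = "zzz")
})

test_that("duplicated ids in a file and malformed numerics fail to read", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,mw,tpsa,alpha", "a,300,50,30", "a,310,60,31"), p)
  expect_error(read_compound_table(p), class = "mlcqsar_validation_error")
  # grouped-digit cells are not silently accepted as numbers
  writeLines(c("compound_id,mw,tpsa,alpha", "a,300,\"74,57\",30"), p)
  expect_error(suppressWarnings(read_compound_table(p)))
  unlink(p)
})
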