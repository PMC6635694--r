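# Measurement tables, normalization ratios and donor selection.

printedTables <- function() {
  t1 <- mtpjMeasurements()
  t2 <- readMeasurementTable(system.file("extdata",
                                         "mtpj_table2_printed.csv",
                                         package = "BoneFrame"))
  list(t1 = t1, t2 = t2)
}

test_that("the packaged ratio table reproduces every printed cell at 4 dp", {
  tb <- printedTables()
  rt <- ratioTable(tb$t1, reference = "H. naledi")
  M <- ratioMatrix(rt, digits = 4)
  measures <- c("length", "width", "height", "surface_area", "volume")
  n_checked <- 0
  for (i in seq_len(nrow(tb$t2))) {
    s <- tb$t2$subject[i]
    b <- tb$t2$bone[i]
    for (m in measures) {
      expect_equal(M[s, paste(b, m, sep = ".")], tb$t2[i, m],
                   tolerance = 1e-9,
                   info = paste(s, b, m))
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 165L) # 11 subjects x 3 bones x 5 measures
})

test_that("spot ratios match hand computation", {
  rt <- ratioTable(mtpjMeasurements(), reference = "H. naledi")
  M <- ratioMatrix(rt, digits = 4)
  expect_equal(M["Basketball player 1", "metatarsal.width"], 1.0888)
  expect_equal(M["Runner", "metatarsal.volume"], 1.2833)
  expect_true(all(M["H. naledi", ] == 1))
})

test_that("the Runner minimizes the mean ratio on the packaged table", {
  rt <- ratioTable(mtpjMeasurements(), reference = "H. naledi")
  expect_equal(selectDonor(rt, "mean_ratio"), "Runner")
  sc <- donorScore(rt, "Runner", "mean_ratio")
  expect_equal(sc, 1.0127, tolerance = 5e-4)
  others <- setdiff(unique(mtpjMeasurements()$subject),
                    c("H. naledi", "Runner"))
  for (s in others)
    expect_gt(donorScore(rt, s, "mean_ratio"), sc)
})

test_that("donor scores behave as defined", {
  tb <- mtpjMeasurements()
  rt <- ratioTable(tb, reference = "H. naledi")
  # reference row: mean ratio 1, mean absolute deviation 0
  expect_equal(donorScore(rt, "H. naledi", "mean_ratio"), 1)
  expect_equal(donorScore(rt, "H. naledi", "mean_abs_dev"), 0)
  expect_error(donorScore(rt, "Nobody"), "unknown subject")
  # scaling one subject's values by c scales its ratios by c
  tb2 <- tb
  sel <- tb2$subject == "Runner"
  for (m in c("length", "width", "height", "surface_area", "volume"))
    tb2[[m]][sel] <- tb2[[m]][sel] * 1.3
  rt2 <- ratioTable(tb2, reference = "H. naledi")
  expect_equal(donorScore(rt2, "Runner", "mean_ratio"),
               1.3 * donorScore(rt, "Runner", "mean_ratio"),
               tolerance = 1e-12)
})

test_that("incomplete tables and ties are handled explicitly", {
  tb <- mtpjMeasurements()
  expect_error(ratioTable(tb[-2, ], reference = "H. naledi"),
               "incomplete")
  expect_error(ratioTable(tb, reference = "Nobody"), "not in table")
  # two identical subjects tie; the first in input order wins, with warning
  dup <- tb[tb$subject == "Runner", ]
  dup$subject <- "Runner copy"
  rt <- ratioTable(rbind(tb, dup), reference = "H. naledi")
  expect_warning(d <- selectDonor(rt), "tie")
  expect_equal(d, "Runner")
  # single-subject table selects that subject
  solo <- rbind(tb[tb$subject == "H. naledi", ],
                tb[tb$subject == "Jumper", ])
  expect_equal(selectDonor(ratioTable(solo, "H. naledi")), "Jumper")
})

test_that("measurement CSV writing and re-reading is lossless", {
  tb <- mtpjMeasurements()
  path <- withr::local_tempfile(fileext = ".csv")
  writeMeasurementTable(tb, path)
  tb2 <- readMeasurementTable(path)
  expect_equal(tb2$volume, tb$volume)
  expect_equal(tb2$subject, tb$subject)
})
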