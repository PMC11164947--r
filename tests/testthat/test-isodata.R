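test_that("CSV parsing handles typographic minus, permil signs and blanks", {
  txt <- paste(
    "label,n,d13c_mean,d13c_sd,d15n_mean,d15n_sd,pct_c,pct_n,cn_ratio",
    "Fresh leaves,5,-15.1,0.7,0.2,1.5,45.5,1.4,34.9",
    "Typographic,3,−14.0‰,0.6,–1.9,1.6,,,",
    sep = "\n"
  )
  tab <- read_group_table(txt, role = "source")
  expect_s3_class(tab, "study_table")
  fresh <- tab[tab$label == "Fresh leaves", ]
  expect_equal(fresh$n, 5)
  expect_equal(fresh$d13c_mean, -15.1)
  expect_equal(fresh$d13c_sd, 0.7)
  expect_equal(fresh$d15n_mean, 0.2)
  expect_equal(fresh$d15n_sd, 1.5)
  expect_equal(fresh$pct_c, 45.5)
  expect_equal(fresh$pct_n, 1.4)
  expect_equal(fresh$cn_ratio, 34.9)
  typo <- tab[tab$label == "Typographic", ]
  expect_equal(typo$d13c_mean, -14.0)
  expect_equal(typo$d15n_mean, -1.9)
  # missing %C/%N are NA, not zero
  expect_true(is.na(typo$pct_c) && is.na(typo$pct_n))
})

test_that("degenerate and invalid inputs are rejected with row context", {
  expect_error(read_group_table("\n", role = "source"))
  bad_sd <- paste(
    "label,n,d13c_mean,d13c_sd,d15n_mean,d15n_sd",
    "Row A,4,-14.0,-0.1,1.0,0.5", sep = "\n"
  )
  expect_error(read_group_table(bad_sd, role = "source"), "Row A")
  bad_n <- paste(
    "label,n,d13c_mean,d13c_sd,d15n_mean,d15n_sd",
    "Row B,0,-14.0,0.1,1.0,0.5", sep = "\n"
  )
  expect_error(read_group_table(bad_n, role = "source"), "Row B")
  both_set <- paste(
    "label,n,d13c_mean,d13c_sd,d15n_mean,d15n_sd,d15n_enrichment",
    "Row C,2,-14.0,0.1,1.0,0.5,2.0", sep = "\n"
  )
  expect_error(read_group_table(both_set, role = "consumer"), "exactly one")
  dup <- paste(
    "label,n,d13c_mean,d13c_sd,d15n_mean,d15n_sd",
    "Row D,2,-14.0,0.1,1.0,0.5",
    "Row D,3,-15.0,0.2,2.0,0.5", sep = "\n"
  )
  expect_error(read_group_table(dup, role = "source"), "duplicated")
})

test_that("packaged tables match the printed values digit for digit", {
  t1 <- load_table1()
  expect_equal(nrow(t1), 8)
  dead <- t1[t1$label == "Dead leaves", ]
  expect_equal(dead$n, 7)
  expect_equal(dead$d13c_mean, -14.0)
  expect_equal(dead$d13c_sd, 0.6)
  expect_equal(dead$d15n_mean, -1.9)
  expect_equal(dead$d15n_sd, 1.6)
  soil <- t1[t1$label == "Soil detritus", ]
  expect_equal(soil$species, "Stipagrostis sabulicola")
  expect_equal(soil$d13c_mean, -14.3)
  expect_equal(soil$d13c_sd, 0.2)
  expect_equal(soil$d15n_mean, 2.0)
  expect_equal(soil$d15n_sd, 1.2)

  t2 <- load_table2()
  expect_equal(nrow(t2), 15)
  halti <- t2[t2$label == "Haltichellinae sp.", ]
  expect_equal(halti$n, 2)
  expect_equal(halti$d13c_mean, -14.0)
  expect_equal(halti$d13c_sd, 0.3)
  expect_equal(halti$d15n_enrichment, 16.7)
  expect_equal(halti$d15n_sd, 0.4)
  zygo <- t2[t2$label == "Zygoribatula sp.", ]
  expect_equal(zygo$d13c_mean, -14.7)
  expect_equal(zygo$d13c_sd, 0.7)
  expect_equal(zygo$d15n_enrichment, 0.05)
  expect_equal(zygo$d15n_sd, 0.6)
  expect_true(zygo$pooled)
  expect_false(t2$pooled[t2$label == "Liposcelis sp."])
  # fixture files are byte-stable
  sums <- unname(tools::md5sum(c(
    system.file("extdata", "table1_basal_resources.csv", package = "isoweb"),
    system.file("extdata", "table2_invertebrates.csv", package = "isoweb")
  )))
  expect_identical(sums, c("ed8beca33ab95d7ed41544a1488431d1",
                           "f3364bea8a459affb5470ada045ea277"))
})

test_that("write/read round-trips preserve every field", {
  norm <- function(x) {
    x <- as.data.frame(x)
    attr(x, "baseline_label") <- NULL
    attr(x, "role") <- NULL
    rownames(x) <- NULL
    x
  }
  for (tab in list(load_table1(), load_table2())) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_group_table(tab, path)
    back <- read_group_table(path, role = attr(tab, "role"))
    expect_equal(norm(back), norm(tab))
  }
})

test_that("rebaseline adds the baseline and inverts exactly", {
  t2 <- load_table2()
  dead <- baseline_spec("Dead leaves", -1.9)
  abs_tab <- rebaseline(t2[t2$baseline == "Dead leaves", ], dead)
  expect_equal(abs_tab$d15n_mean[abs_tab$label == "Zygoribatula sp."], -1.85)
  # SDs unchanged (baseline treated as fixed)
  expect_equal(abs_tab$d15n_sd,
               t2$d15n_sd[t2$baseline == "Dead leaves"])
  # zero enrichment lands on the baseline
  one <- data.frame(label = "x", n = 1, d13c_mean = -14, d13c_sd = 0,
                    d15n_enrichment = 0, d15n_sd = 0)
  expect_equal(rebaseline(study_table(one, "consumer"), dead)$d15n_mean, -1.9)
  nara <- baseline_spec("Litter (dead stem)", 4.2)
  hz <- rebaseline(t2[t2$label == "Hycleus zigzagus", ], nara)
  expect_equal(hz$d15n_mean, 14.6)
  # apply/remove is an exact inverse for arbitrary baselines
  for (b in c(-1.9, 0, 4.2, 12.345)) {
    bl <- baseline_spec("b", b)
    there <- rebaseline(t2[t2$baseline == "Dead leaves", ], bl)
    back <- remove_baseline(there, bl)
    expect_equal(back$d15n_enrichment,
                 t2$d15n_enrichment[t2$baseline == "Dead leaves"])
  }
  # double-baselining guard
  expect_error(rebaseline(abs_tab, dead), "already")
})

test_that("baseline SD propagation adds in quadrature when requested", {
  t2 <- load_table2()
  bl <- baseline_spec("Dead leaves", -1.9, d15n_sd = 1.6)
  out <- rebaseline(t2[t2$label == "Zygoribatula sp.", ], bl,
                    propagate = TRUE)
  expect_equal(out$d15n_sd, sqrt(0.6^2 + 1.6^2))
})
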