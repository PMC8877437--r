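# fixtures built in code; values use short decimals so CSV round-trips are
# exact
rand_intensity <- function(nf = 6, ns = 5, seed = 11) {
  set.seed(seed)
  vals <- matrix(round(runif(nf * ns, 0, 1e4), 3), nf,
                 dimnames = list(sprintf("f%02d", 1:nf),
                                 sprintf("s%02d", 1:ns)))
  intensity_matrix(vals, mz = round(runif(nf, 100, 500), 4),
                   rt = round(runif(nf, 0, 600), 2))
}

test_that("intensity matrix CSV reader validates and round-trips", {
  m <- rand_intensity()
  path <- withr::local_tempfile(fileext = ".csv")
  write_intensity_matrix(m, path)
  m2 <- read_intensity_matrix(path, rt_column = "rt")
  expect_identical(m2$values, m$values)
  expect_identical(m2$mz, m$mz)
  expect_identical(m2$rt, m$rt)

  # basic shape from a handwritten 3 x 4 file
  tiny <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,mz,sA,sB,sC,sD",
               "x1,100.5,1,2,3,4",
               "x2,200.25,5,6,7,8",
               "x3,300.125,9,10,11,12"), tiny)
  t1 <- read_intensity_matrix(tiny)
  expect_equal(dim(t1), c(3L, 4L))
  expect_equal(feature_ids(t1), c("x1", "x2", "x3"))
  expect_equal(sample_ids(t1), c("sA", "sB", "sC", "sD"))
  expect_equal(t1$mz, c(100.5, 200.25, 300.125))
})

test_that("reader errors name the offending column or cell", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,sA,sB", "x1,1,2"), bad)
  expect_error(read_intensity_matrix(bad), "'mz' not found")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,mz,sA,sB", "x1,100,1,-3"), neg)
  expect_error(read_intensity_matrix(neg), "x1.*sB|sB.*x1")

  txt <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,mz,sA,sB", "x1,100,1,oops"), txt)
  expect_error(read_intensity_matrix(txt), "x1")
  expect_error(read_intensity_matrix(txt), "sB")
})

test_that("blank cells are imputed as zero with a reported count", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,mz,sA,sB,sC", "x1,100,1,,3", "x2,200,,5,6"), path)
  expect_message(m <- read_intensity_matrix(path), "2 blank cell")
  expect_equal(unname(m$values["x1", "sB"]), 0)
  expect_equal(unname(m$values["x2", "sA"]), 0)
})

test_that("count matrix reader handles both feature kinds and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,sA,sB,sC,sD", "otu1,3,0,2,9", "otu2,1,1,4,0"), path)
  taxa <- read_count_matrix(path, feature_kind = "taxon")
  enz <- read_count_matrix(path, feature_kind = "enzyme")
  expect_equal(taxa$feature_kind, "taxon")
  expect_equal(enz$feature_kind, "enzyme")
  expect_identical(taxa$values, enz$values)

  out <- withr::local_tempfile(fileext = ".csv")
  write_count_matrix(taxa, out)
  expect_identical(read_count_matrix(out)$values, taxa$values)
})

test_that("MGF reader applies cohort tags, sorts peaks, and round-trips", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=sp1", "PEPMASS=301.1 12345",
               "RTINSECONDS=12.5",
               "120.05 10", "80.02 5", "200.11 3",  # deliberately unsorted
               "END IONS", "",
               "BEGIN IONS", "TITLE=sp2", "PEPMASS=180.2",
               "90.01 7", "END IONS"), path)
  sp <- read_spectra(path, cohort_tag = "gut")
  expect_length(sp, 2)
  expect_equal(vapply(sp, function(s) s$cohort, character(1)),
               c("gut", "gut"))
  expect_equal(sp[[1]]$precursor_mz, 301.1)
  expect_equal(sp[[1]]$peaks[, "mz"], c(80.02, 120.05, 200.11),
               ignore_attr = TRUE)
  expect_equal(sp[[1]]$retention_time, 12.5)

  out <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, out)
  sp2 <- read_spectra(out, cohort_tag = "gut")
  for (k in 1:2) {
    expect_equal(sp2[[k]]$peaks, sp[[k]]$peaks, tolerance = 1e-12)
    expect_equal(sp2[[k]]$precursor_mz, sp[[k]]$precursor_mz)
    expect_equal(sp2[[k]]$spectrum_id, sp[[k]]$spectrum_id)
  }
})

test_that("MGF scans without a precursor are skipped and counted", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=good", "PEPMASS=100.5", "50 1",
               "END IONS",
               "BEGIN IONS", "TITLE=nopm", "60 2", "END IONS"), path)
  expect_warning(sp <- read_spectra(path, "food"), "no PEPMASS")
  expect_length(sp, 1)
  expect_equal(attr(sp, "n_skipped"), 1L)
})

test_that("rare-feature filter uses the two-sample presence boundary and is idempotent", {
  vals <- rbind(one = c(5, 0, 0, 0),   # present in 1 sample -> dropped
                two = c(5, 7, 0, 0),   # present in exactly 2 -> retained
                all = c(1, 2, 3, 4))
  colnames(vals) <- paste0("s", 1:4)
  m <- intensity_matrix(vals, mz = c(100, 200, 300))
  f <- filter_rare_features(m)
  expect_equal(feature_ids(f), c("two", "all"))
  expect_equal(f$mz, c(200, 300))
  expect_identical(filter_rare_features(f), f)

  zero <- intensity_matrix(matrix(0, 2, 4, dimnames = list(c("a", "b"),
                                                           paste0("s", 1:4))),
                           mz = c(1, 2))
  expect_equal(nrow(filter_rare_features(zero)$values), 0L)
})

test_that("sample alignment intersects ids canonically and is symmetric", {
  mk_int <- function(samples) {
    v <- matrix(seq_len(2 * length(samples)), 2,
                dimnames = list(c("f1", "f2"), samples))
    intensity_matrix(v, mz = c(100, 200))
  }
  mk_cnt <- function(samples) {
    v <- matrix(seq_len(2 * length(samples)), 2,
                dimnames = list(c("o1", "o2"), samples))
    count_matrix(v)
  }
  # disjoint -> error stating overlap
  expect_error(align_samples(mk_int(c("a", "b", "c")),
                             mk_cnt(c("x", "y", "z"))), "0 shared")
  # identical sets -> unchanged values, canonical column order
  a <- mk_int(c("c", "a", "b"))
  b <- mk_cnt(c("b", "c", "a"))
  al <- align_samples(a, b)
  expect_equal(sample_ids(al$molecules), c("a", "b", "c"))
  expect_equal(sample_ids(al$microbes), c("a", "b", "c"))
  expect_equal(al$molecules$values[, "a"], a$values[, "a"])
  # partial overlap: 5 of 8
  a8 <- mk_int(paste0("s", 1:8))
  b5 <- mk_cnt(paste0("s", 4:8))
  al2 <- align_samples(a8, b5)
  expect_equal(sample_ids(al2$molecules), paste0("s", 4:8))
  expect_equal(sample_ids(al2$microbes), paste0("s", 4:8))
  # symmetry of the shared-id set
  al3 <- align_samples(mk_int(paste0("s", 4:8)), mk_cnt(paste0("s", 1:8)))
  expect_setequal(sample_ids(al2$molecules), sample_ids(al3$molecules))
})
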