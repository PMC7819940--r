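test_that("wavelength grids include both endpoints at constant spacing", {
  ex <- make_grid(250, 450, 5)
  em <- make_grid(250, 600, 1)
  expect_length(ex, 41)
  expect_length(em, 351)
  expect_equal(as.numeric(ex)[1], 250)
  expect_equal(as.numeric(ex)[41], 450)
  expect_true(all(abs(diff(as.numeric(em)) - 1) < 1e-12))

  single <- make_grid(250, 250, 5)
  expect_length(single, 1)
  expect_equal(as.numeric(single), 250)

  expect_error(make_grid(250, 452, 5), "not divisible")
  expect_error(make_grid(250, 240, 5), "end")
  expect_error(make_grid(250, 450, 0), "step")
})

test_that("EEM CSV writing and reading are exact inverses", {
  e <- random_eem(seed = 42, na_frac = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eem_csv(e, path)
  back <- read_eem_csv(path, sample_id = e$sample_id)
  expect_identical(back$intensity, e$intensity)
  expect_equal(as.numeric(back$ex_grid), as.numeric(e$ex_grid))
  expect_equal(as.numeric(back$em_grid), as.numeric(e$em_grid))

  # small hand-built file: ex header 250,255; em header 250,251,252
  toy <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",250,255", "250,1,2", "251,3,4", "252,5,"), toy)
  te <- read_eem_csv(toy)
  expect_equal(dim(te$intensity), c(3L, 2L))
  expect_equal(te$intensity[1, ], c(1, 2))
  expect_true(is.na(te$intensity[3, 2]))
})

test_that("malformed EEM CSV files are rejected with located errors", {
  bad_step <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",250,255,261", "250,1,2,3", "251,4,5,6"), bad_step)
  expect_error(read_eem_csv(bad_step), "step not constant")

  unsorted <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",255,250", "250,1,2"), unsorted)
  expect_error(read_eem_csv(unsorted), "not ascending")

  non_num <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",250,255", "250,1,x"), non_num)
  expect_error(read_eem_csv(non_num), "row 2, column 3")
})

test_that("stacks enforce shared grids and unique scan identity", {
  e1 <- random_eem(1, sample_id = "A")
  e2 <- random_eem(2, sample_id = "B")
  st <- build_stack(list(e1, e2))
  expect_equal(unname(stack_dims(st)), c(9L, 36L, 2L))
  expect_length(build_stack(list(e1)), 1L)

  other_grid <- random_eem(3, em = make_grid(250, 600, 5), sample_id = "C")
  expect_error(build_stack(list(e1, other_grid)), "grid mismatch.*C")
  dup <- random_eem(4, sample_id = "A")
  expect_error(build_stack(list(e1, dup)), "duplicate")
  expect_error(build_stack(list(e1), reference = c(Z = 1)), "lacks sample")
})

test_that("replicate averaging means observed cells and is idempotent", {
  ex <- make_grid(300, 310, 5); em <- make_grid(300, 320, 10)
  z <- function(v) matrix(v, 3, 3)
  reps <- list(eem(z(1), ex, em, "s", 1), eem(z(2), ex, em, "s", 2),
               eem(z(3), ex, em, "s", 3))
  avg <- average_replicates(build_stack(reps))
  expect_length(avg, 1L)
  expect_true(all(avg$eems[[1]]$intensity == 2))

  za <- z(5); za[2, 2] <- NA
  zb <- z(7); zb[1, 1] <- NA; zb[2, 2] <- NA
  avg2 <- average_replicates(build_stack(list(
    eem(za, ex, em, "s", 1), eem(zb, ex, em, "s", 2))))
  got <- avg2$eems[[1]]$intensity
  expect_equal(got[1, 1], 5)          # missing replicate skipped
  expect_true(is.na(got[2, 2]))       # missing in all replicates
  expect_equal(got[3, 3], 6)

  expect_identical(average_replicates(avg)$eems[[1]]$intensity,
                   avg$eems[[1]]$intensity)
})

test_that("unfolding is excitation-major and folds back exactly", {
  ex <- make_grid(250, 255, 5); em <- make_grid(250, 260, 10)
  e <- eem(matrix(c(1, 3, 2, 4), 2, 2), ex, em, "s")
  uf <- unfold(build_stack(list(e)))
  expect_equal(unname(uf$X[1, ]), c(1, 3, 2, 4))
  expect_equal(uf$vmap$ex, c(250, 250, 255, 255))
  expect_equal(uf$vmap$em, c(250, 260, 250, 260))

  refolded <- fold(uf$X[1, ], uf$vmap, ex, em)
  expect_equal(unname(refolded), unname(e$intensity))
})

test_that("fold/unfold round-trips retained cells for arbitrary stacks", {
  for (seed in 1:5) {
    eems <- lapply(1:3, function(k)
      random_eem(seed * 10 + k, sample_id = paste0("S", k),
                 na_frac = if (seed %% 2) 0.15 else 0))
    # missing cells must coincide across scans for the drop policy to be
    # lossless per retained cell; imitate scatter excision
    na_mask <- is.na(eems[[1]]$intensity)
    eems <- lapply(eems, function(e) {
      e$intensity[na_mask] <- NA
      if (all(is.na(e$intensity))) e$intensity[1, 1] <- 1
      e
    })
    st <- build_stack(eems)
    uf <- unfold(st, missing = "drop")
    for (k in seq_along(eems)) {
      m <- fold(uf$X[k, ], uf$vmap, st$ex_grid, st$em_grid)
      obs <- !is.na(m)
      expect_identical(unname(m[obs]), unname(eems[[k]]$intensity[obs]))
    }
  }
})

test_that("column drop and impute policies handle missing cells", {
  ex <- make_grid(250, 255, 5); em <- make_grid(250, 260, 10)
  z1 <- matrix(c(1, 3, 2, 4), 2, 2); z1[1, 1] <- NA
  z2 <- matrix(c(5, 7, 6, 8), 2, 2)
  st <- build_stack(list(eem(z1, ex, em, "a"), eem(z2, ex, em, "b")))
  expect_equal(ncol(unfold(st, "drop")$X), 3L)
  ui <- unfold(st, "impute")
  expect_equal(ncol(ui$X), 4L)
  expect_equal(unname(ui$X[1, 1]), 5)  # imputed from the only observed scan
})

test_that("stack manifests round-trip through disk", {
  eems <- lapply(1:2, function(k) lapply(1:2, function(r)
    random_eem(k * 5 + r, sample_id = paste0("S", k), replicate_id = r)))
  st <- build_stack(unlist(eems, recursive = FALSE),
                    reference = c(S1 = 40, S2 = 80))
  dir <- withr::local_tempdir()
  write_stack_csv(st, dir)
  back <- read_stack_csv(dir)
  expect_length(back, 4L)
  expect_equal(back$reference, st$reference)
  expect_identical(back$eems[[3]]$intensity, st$eems[[3]]$intensity)
  expect_equal(stack_reference(back), c(40, 40, 80, 80))
})
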