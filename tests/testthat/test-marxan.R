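test_that("export writes the three tables with one puvspr row per presence", {
  ins <- fig2_instance()
  d <- withr::local_tempdir()
  w <- suppressWarnings(normalize_weights(ins$tree))  # fixture is non-clock
  export_marxan(ins$incidence, w, dir = d)
  expect_true(all(file.exists(file.path(d, c("pu.dat", "spec.dat",
                                             "puvspr.dat")))))
  puvspr <- read.csv(file.path(d, "puvspr.dat"))
  expect_equal(nrow(puvspr), sum(ins$incidence$matrix))
  expect_true(all(puvspr$amount == 1))
  expect_false(is.unsorted(puvspr$pu))
  spec <- read.csv(file.path(d, "spec.dat"))
  expect_true(all(spec$target == 1))
  expect_equal(spec$name, ins$incidence$branch_id)
})

test_that("export -> import round trip is lossless", {
  ins <- random_instance(71, n_tips = 12, n_pus = 6, endemism = 0.2)
  w <- ins$weights
  d <- withr::local_tempdir()
  export_marxan(ins$incidence, w, costs = seq(1, 2, length.out = 6), dir = d)
  back <- import_marxan(d)
  expect_equal(back$incidence$matrix, ins$incidence$matrix)
  # lengths and spf are serialised to 10 significant digits
  expect_equal(back$incidence$length, ins$incidence$length, tolerance = 1e-9)
  expect_equal(back$spf, w$w, tolerance = 1e-9)
  expect_equal(back$costs, seq(1, 2, length.out = 6))
})

test_that("writers are byte-deterministic", {
  ins <- random_instance(72)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_marxan(ins$incidence, ins$weights, dir = d1)
  export_marxan(ins$incidence, ins$weights, dir = d2)
  for (f in c("pu.dat", "spec.dat", "puvspr.dat", "branch_ids.csv",
              "pu_ids.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("import validates files, columns and id references", {
  d <- withr::local_tempdir()
  expect_error(import_marxan(d), "missing Marxan file")
  writeLines(c("id,cost", "1,1", "2,1"), file.path(d, "pu.dat"))
  writeLines(c("id,target,spf,name", "1,1,0.5,b0001"), file.path(d, "spec.dat"))
  writeLines(c("species,pu,amount", "1,9,1"), file.path(d, "puvspr.dat"))
  expect_error(import_marxan(d), "unknown pu id\\(s\\): 9")
  writeLines(c("species,pu,amount", "7,1,1"), file.path(d, "puvspr.dat"))
  expect_error(import_marxan(d), "unknown species id\\(s\\): 7")
  writeLines(c("id,cost,extra", "1,1,0"), file.path(d, "pu.dat"))
  expect_error(import_marxan(d), "unknown column")
})

test_that("hand-written tables load with the nesting flag false", {
  d <- withr::local_tempdir()
  writeLines(c("id,cost", "1,1", "2,1", "3,1"), file.path(d, "pu.dat"))
  writeLines(c("id,target,spf,name", "1,1,0.5,f1", "2,1,0.25,f2"),
             file.path(d, "spec.dat"))
  # rows {p1,p2} and {p2,p3}: overlapping but not nested
  writeLines(c("species,pu,amount", "1,1,1", "1,2,1", "2,2,1", "2,3,1"),
             file.path(d, "puvspr.dat"))
  back <- import_marxan(d)
  expect_false(back$dominance)
  expect_equal(dim(back$incidence$matrix), c(2L, 3L))
  # and a nested pair reads back as consistent
  writeLines(c("species,pu,amount", "1,1,1", "1,2,1", "2,2,1"),
             file.path(d, "puvspr.dat"))
  expect_true(import_marxan(d)$dominance)
})

test_that("tab-delimited Marxan files are accepted on read", {
  d <- withr::local_tempdir()
  writeLines(c("id\tcost", "1\t1"), file.path(d, "pu.dat"))
  writeLines(c("id\ttarget\tspf\tname", "1\t1\t1\tf1"), file.path(d, "spec.dat"))
  writeLines(c("species\tpu\tamount", "1\t1\t1"), file.path(d, "puvspr.dat"))
  back <- import_marxan(d)
  expect_equal(back$incidence$n_pu, 1L)
  expect_equal(unname(back$incidence$n_b), 1)
})
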