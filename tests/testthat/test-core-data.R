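# Domain containers, delimited-text and GIFTI I/O, aggregation,
# hemisphere concatenation and concept splitting.

test_that("concept matrix text I/O round-trips bit-exactly and validates input", {
  # identity round-trip of a small labelled table
  cm <- concept_matrix(matrix(c(1, 2, 3, 4, 5, 6), 3, 2),
                       concept_ids = c("ant", "bee", "cat"),
                       feature_labels = c("f1", "f2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_concept_matrix(cm, path)
  back <- read_concept_matrix(path)
  expect_identical(unclass(back), unclass(cm))

  # seeded random full-precision round-trip, tsv and csv
  set.seed(41)
  rnd <- concept_matrix(matrix(rnorm(20), 5, 4))
  for (fmt in c("tsv", "csv")) {
    p <- withr::local_tempfile()
    write_concept_matrix(rnd, p, format = fmt)
    expect_identical(unclass(read_concept_matrix(p, format = fmt)),
                     unclass(rnd))
  }

  # duplicated concept id is rejected
  writeLines(c("concept_id\tf1", "a\t1", "a\t2"), path)
  expect_error(read_concept_matrix(path), "duplicate concept id")

  # non-numeric cells are reported with their location
  writeLines(c("concept_id\tf1\tf2", "a\t1\t2", "b\tx\t3"), path)
  expect_error(read_concept_matrix(path), "concept 'b', feature 'f1'")
})

test_that("constructors enforce the container invariants", {
  expect_error(concept_matrix(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(concept_matrix(matrix(1:4, 2, 2), concept_ids = c("a", "a")),
               "unique")
  expect_error(neural_responses(matrix(1, 2, 2),
                                data.frame(hemisphere = "left",
                                           vertex = c(1, 1))),
               "unique")
  expect_error(vertex_mask(rep(FALSE, 5)), "at least one vertex")
  expect_error(vertex_map(1:3, left_index(4)), "length")
  expect_error(split_spec(1:3, 3:5), "disjoint")
  expect_error(split_spec(integer(0), 1:2), "non-empty")
})

test_that("average_by_group computes first-appearance-ordered group means", {
  cm <- concept_matrix(rbind(c(1, 3), c(2, 4)), c("t1", "t2"), c("f1", "f2"))
  out <- average_by_group(cm, c("g", "g"))
  expect_equal(unname(unclass(out)), rbind(c(1.5, 3.5)))  # hand mean

  # singleton groups: identity
  idm <- average_by_group(cm, c("a", "b"))
  expect_equal(unname(unclass(idm)), unname(unclass(cm)))

  # 12 equal rows per group collapse to the common row
  y <- neural_responses(matrix(rep(c(2, -1, 0.5), each = 12), 12, 3),
                        left_index(3))
  avg <- average_by_group(y, rep("concept", 12))
  expect_equal(unname(avg$values), rbind(c(2, -1, 0.5)))

  # idempotent on already-aggregated data
  twice <- average_by_group(average_by_group(cm, c("a", "b")), c("a", "b"))
  expect_equal(unclass(twice), unclass(average_by_group(cm, c("a", "b"))))

  expect_error(average_by_group(cm, character(0)), "group label")
})

test_that("hemisphere concatenation tags columns and inverts exactly", {
  set.seed(7)
  l <- random_responses(4, 3, "left")
  r <- random_responses(4, 5, "right")
  both <- concat_hemispheres(l, r)
  expect_equal(dim(both), c(4L, 8L))
  expect_equal(both$vertex_index$hemisphere, rep(c("left", "right"), c(3, 5)))

  parts <- split_hemispheres(both)
  expect_equal(parts$left$values, l$values)
  expect_equal(parts$right$values, r$values)
  expect_equal(parts$right$vertex_index, r$vertex_index,
               ignore_attr = "row.names")

  # mismatched concept order is rejected
  r2 <- neural_responses(r$values[4:1, ], r$vertex_index,
                         concept_ids = rev(concept_ids(r)))
  expect_error(concat_hemispheres(l, r2), "concept ids")
})

test_that("concept splitting partitions rows and recombination restores input", {
  set.seed(8)
  cm <- concept_matrix(matrix(rnorm(720 * 2), 720, 2))
  spec <- first_last_split(720, 480)
  parts <- split_concepts(cm, spec)
  expect_equal(nrow(parts$train), 480L)
  expect_equal(nrow(parts$test), 240L)
  recombined <- rbind(unclass(parts$train), unclass(parts$test))
  expect_identical(recombined, unclass(cm))

  expect_error(first_last_split(10, 10), "non-empty")
  expect_error(split_concepts(cm, split_spec(1:700, 700:720)), "disjoint")
  expect_error(split_concepts(concept_matrix(matrix(1:4, 2, 2)),
                              split_spec(1, 3)),
               "exceed")
})

test_that("GIFTI mesh and functional map I/O are lossless", {
  mesh <- icosphere(1, hemisphere = "right")
  path <- withr::local_tempfile(fileext = ".surf.gii")
  write_mesh(mesh, path)
  back <- read_mesh(path)
  expect_identical(back$coordinates, mesh$coordinates)
  expect_identical(back$triangles, mesh$triangles)
  expect_identical(back$hemisphere, "right")

  # out-of-range triangle index is refused at construction
  expect_error(surface_mesh(mesh$coordinates,
                            rbind(mesh$triangles, c(1L, 2L, 99L))),
               "out of range")
  # degenerate triangle is refused
  expect_error(surface_mesh(mesh$coordinates,
                            rbind(mesh$triangles, c(3L, 3L, 4L))),
               "degenerate")

  set.seed(9)
  mask <- vertex_mask(c(rep(TRUE, 30), rep(FALSE, 12)), "left")
  vals <- rnorm(30)
  vm <- vertex_map(vals, left_index(30), name = "R2")
  for (ext in c(".func.gii", ".tsv")) {
    p <- withr::local_tempfile(fileext = ext)
    write_vertex_map(vm, mask, p)
    rt <- read_vertex_map(p, mask)
    expect_identical(rt$values, vals)
    expect_identical(rt$name, "R2")
    # mask written alongside, excluded vertices zero on disk
    expect_true(file.exists(paste0(p, ".mask.tsv")))
    full_mask <- vertex_mask(rep(TRUE, 42), "left")
    expect_equal(read_vertex_map(p, full_mask)$values[31:42], rep(0, 12))
  }

  # all-zero map round-trips to all-zero
  zp <- withr::local_tempfile(fileext = ".func.gii")
  zmap <- vertex_map(rep(0, 30), left_index(30), "zero")
  write_vertex_map(zmap, mask, zp)
  expect_identical(read_vertex_map(zp, mask)$values, rep(0, 30))

  # map length inconsistent with the mask is an error
  expect_error(write_vertex_map(vertex_map(rnorm(10), left_index(10)),
                                mask, withr::local_tempfile(fileext = ".tsv")),
               "mask-included")
})

test_that("mask TSV I/O round-trips", {
  mask <- vertex_mask(c(TRUE, FALSE, TRUE, TRUE), "right")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_vertex_mask(mask, p)
  back <- read_vertex_mask(p, hemisphere = "right")
  expect_identical(back$included, mask$included)
})
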