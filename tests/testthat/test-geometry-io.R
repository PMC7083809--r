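test_that("FreeSurfer ASC reader parses a minimal closed surface and
           round-trips exactly", {
  f <- withr::local_tempfile(fileext = ".asc")
  write_tetra_asc(f)
  sm <- read_freesurfer_asc(f)
  expect_s3_class(sm, "surface_mesh")
  expect_equal(nrow(sm$vertices), 4L)
  expect_equal(nrow(sm$triangles), 4L)
  expect_true(is_closed_surface(sm))
  # mm on disk -> m internally
  expect_equal(max(sm$vertices), 1e-3)

  # round trip is exact, including random coordinates at full precision
  set.seed(42)
  rnd <- surface_mesh(matrix(rnorm(30), 10), cbind(1:8, 2:9, 3:10), "rnd")
  f2 <- withr::local_tempfile(fileext = ".asc")
  write_freesurfer_asc(rnd, f2)
  back <- read_freesurfer_asc(f2)
  expect_identical(back$triangles, rnd$triangles)
  expect_equal(back$vertices, rnd$vertices, tolerance = 0)
})

test_that("ASC reader rejects malformed files with parse errors", {
  f <- withr::local_tempfile(fileext = ".asc")
  # declares 5 vertices but lists 4
  writeLines(c("5 4", "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "0 2 1", "0 1 3", "1 2 3", "0 3 2"), f)
  expect_error(read_freesurfer_asc(f), "parse error")
  writeLines(c("4 1", "0 0 0", "1 0 0", "0 1 0", "x y z", "0 1 2"), f)
  expect_error(read_freesurfer_asc(f), "non-numeric")
})

test_that("DAT pair reader matches the ASC fixture and validates indices", {
  fa <- withr::local_tempfile(fileext = ".asc")
  write_tetra_asc(fa)
  ref <- read_freesurfer_asc(fa)
  fn <- withr::local_tempfile(fileext = ".dat")
  ft <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0 0 0", "1 0 0", "0 1 0", "0 0 1"), fn)
  writeLines(c("1 3 2", "1 2 4", "2 3 4", "1 4 3"), ft)  # 1-based on disk
  sm <- read_dat_pair(fn, ft)
  expect_equal(sm$vertices, ref$vertices)
  expect_identical(sm$triangles, ref$triangles)

  writeLines(c("1 3 5", "1 2 4"), ft)  # node 5 of 4
  expect_error(read_dat_pair(fn, ft), "out of range")

  writeLines(character(0), ft)
  expect_warning(sm0 <- read_dat_pair(fn, ft), "empty triangle")
  expect_equal(nrow(sm0$triangles), 0L)
})

test_that("readers are insensitive to CRLF line endings and trailing
           whitespace", {
  f1 <- withr::local_tempfile(fileext = ".asc")
  write_tetra_asc(f1)
  ref <- read_freesurfer_asc(f1)
  f2 <- withr::local_tempfile(fileext = ".asc")
  writeLines(paste0(readLines(f1), "  \r"), f2, sep = "\n")
  alt <- read_freesurfer_asc(f2)
  expect_equal(alt$vertices, ref$vertices)
  expect_identical(alt$triangles, ref$triangles)
})

write_segmentation_fixture <- function(dir, n_comp = 5,
                                       names = c("white", "grey", "csf",
                                                 "skull", "scalp"),
                                       extra = "") {
  asc <- file.path(dir, "surf.asc")
  write_tetra_asc(asc)
  ini <- file.path(dir, "seg.ini")
  sects <- vapply(seq_len(n_comp), function(i)
    sprintf("[%s]\nfiles = surf.asc\n%s", names[i], extra), "")
  writeLines(rev(sects), ini)  # outermost first: scalp ... white
  ini
}

test_that("segmentation INI applies the default conductivity table", {
  dir <- withr::local_tempdir()
  ini <- write_segmentation_fixture(dir)
  seg <- read_segmentation_ini(ini)
  expect_length(seg$compartments, 5L)
  byname <- setNames(vapply(seg$compartments, `[[`, 0, "conductivity"),
                     vapply(seg$compartments, `[[`, "", "name"))
  expect_equal(byname[["grey"]], 0.33)
  expect_equal(byname[["white"]], 0.14)
  expect_equal(byname[["skull"]], 0.0064)
  expect_equal(byname[["scalp"]], 0.43)
  expect_equal(byname[["csf"]], 1.79)  # documented package default
  # outermost-first order preserved; default priorities decrease inward
  prios <- vapply(seg$compartments, `[[`, 0L, "priority")
  expect_true(all(diff(prios) < 0))
})

test_that("segmentation INI merges sub-meshes and enforces the
           27-compartment limit", {
  dir <- withr::local_tempdir()
  write_tetra_asc(file.path(dir, "lh.asc"))
  write_tetra_asc(file.path(dir, "rh.asc"))
  ini <- file.path(dir, "two.ini")
  writeLines(c("[grey]", "files = lh.asc, rh.asc", "active = 1"), ini)
  seg <- read_segmentation_ini(ini)
  expect_length(seg$compartments[[1]]$sub_meshes, 2L)
  expect_true(seg$compartments[[1]]$active)

  ini28 <- file.path(dir, "many.ini")
  writeLines(unlist(lapply(1:28, function(i)
    c(sprintf("[c%02d]", i), "files = lh.asc", "conductivity = 1"))), ini28)
  expect_error(read_segmentation_ini(ini28), "27")

  ini_missing <- file.path(dir, "missing.ini")
  writeLines(c("[grey]", "files = absent.asc"), ini_missing)
  expect_error(read_segmentation_ini(ini_missing), "absent.asc")
})

test_that("parcellation reader maps labels through the colortable", {
  dir <- withr::local_tempdir()
  pts <- file.path(dir, "points.asc")
  ct <- file.path(dir, "colortable.txt")
  writeLines(c("0 0 0 1", "10 0 0 1", "0 10 0 2"), pts)
  writeLines(c("1 A", "2 B"), ct)
  p <- read_parcellation(pts, ct)
  expect_equal(length(unique(p$labels)), 2L)
  expect_equal(p$colortable$name, c("A", "B"))
  expect_equal(p$points[2, 1], 0.010)  # mm -> m

  writeLines(c("0 0 0 1", "10 0 0 3"), pts)
  expect_error(read_parcellation(pts, ct), "3")

  # 36-region colortable loads with 36 names
  writeLines(sprintf("%d region_%02d", 1:36, 1:36), ct)
  writeLines(sprintf("%g 0 0 %d", seq_len(36), 1:36), pts)
  p36 <- read_parcellation(pts, ct)
  expect_equal(nrow(p36$colortable), 36L)
  expect_equal(length(unique(p36$labels)), 36L)
})

test_that("project container round-trips numeric state bit-exactly", {
  f <- withr::local_tempfile(fileext = ".rds")
  set.seed(1)
  L <- matrix(rnorm(120), 10, 12)
  state <- list(leadfield = L, params = list(beta = 1.5),
                mesh = ref_tet_mesh())
  save_project(state, f)
  back <- load_project(f)
  expect_identical(back$leadfield, L)
  expect_identical(back$mesh$nodes, state$mesh$nodes)

  expect_error(load_project(file.path(tempdir(), "nope.rds")), "not found")

  # partial state round-trips without demanding other fields
  f2 <- withr::local_tempfile(fileext = ".rds")
  save_project(list(mesh = ref_tet_mesh()), f2)
  expect_named(load_project(f2), "mesh")

  # version check
  saveRDS(list(format = "neurofem_project", version = 99L, state = list()), f2)
  expect_error(load_project(f2), "version")
})

test_that("DAT pair writer round-trips", {
  sm <- unit_tetra_surface()
  fn <- withr::local_tempfile(); ft <- withr::local_tempfile()
  write_dat_pair(sm, fn, ft)
  back <- read_dat_pair(fn, ft)
  expect_equal(back$vertices, sm$vertices)
  expect_identical(back$triangles, sm$triangles)
})
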