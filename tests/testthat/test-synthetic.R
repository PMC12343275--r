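# The synthetic smear generator: signatures, rendering, masks, manifests.

test_that("default signatures are five distinct, learnable recipes", {
  sigs <- apl_signatures()
  expect_length(sigs, 5L)
  expect_setequal(names(sigs), c("PML-RARA", "TTMV-RARA", "NPM1-RARA",
                                 "STAT5B-RARA", "NUP98-RARG"))
  # pairwise different in at least two signature fields
  fields <- c("nucleus_shape", "nucleus_fraction", "cytoplasm_hue",
              "nucleus_hue", "granularity_density", "rod_count_range")
  for (i in 1:4) for (j in (i + 1):5) {
    ndiff <- sum(vapply(fields, function(f)
      !identical(sigs[[i]][[f]], sigs[[j]][[f]]), logical(1)))
    expect_gte(ndiff, 2)
  }
  # exactly one class always carries rod inclusions
  has_rods <- vapply(sigs, function(s) s$rod_count_range[1] >= 1, logical(1))
  expect_identical(names(sigs)[has_rods], "PML-RARA")
})

test_that("render_cell draws rods only when requested, inside the cell", {
  sigs <- apl_signatures()
  no_rod <- render_cell(sigs[["STAT5B-RARA"]], c(64, 64), seed = 11)
  expect_false(any(no_rod$rod_mask))

  pml <- render_cell(sigs[["PML-RARA"]], c(128, 128), seed = 7)
  expect_true(any(pml$rod_mask))
  # rod count within the signature's range, by an independent
  # flood-fill component count
  ncomp <- count_components(pml$rod_mask)
  expect_gte(ncomp, 1)
  expect_lte(ncomp, 3)
  # masks are consistent and dimensioned like the image
  for (s in c(3, 7, 21)) {
    smp <- render_cell(sigs[["PML-RARA"]], c(96, 96), seed = s)
    expect_false(any(smp$rod_mask & !smp$cell_mask))
    expect_identical(dim(smp$cell_mask), dim(smp$pixels)[1:2])
    expect_identical(dim(smp$rod_mask), dim(smp$pixels)[1:2])
  }
})

test_that("rendering is bit-reproducible and bounded", {
  sig <- apl_signatures()[["TTMV-RARA"]]
  a <- render_cell(sig, c(64, 64), seed = 123)
  b <- render_cell(sig, c(64, 64), seed = 123)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$cell_mask, b$cell_mask)
  expect_true(all(a$pixels >= 0L & a$pixels <= 255L))
  # a different seed moves the pixels
  c2 <- render_cell(sig, c(64, 64), seed = 124)
  expect_false(identical(a$pixels, c2$pixels))
})

test_that("render_cell rejects images too small for a cell", {
  expect_error(render_cell(apl_signatures()[[1]], c(16, 16), seed = 1),
               "32x32")
})

test_that("generate_dataset books counts exactly and reproducibly", {
  # empty spec -> empty manifest
  empty <- dataset_spec(per_class_counts = c("PML-RARA" = 0L),
                        image_size = c(32, 32))
  expect_identical(nrow(generate_dataset(empty)$manifest), 0L)

  spec <- dataset_spec(per_class_counts = c("PML-RARA" = 3L,
                                            "TTMV-RARA" = 2L),
                       image_size = c(48, 48), master_seed = 5L)
  ds <- generate_dataset(spec)
  expect_identical(nrow(ds$manifest), 5L)
  expect_identical(sum(ds$manifest$label == "PML-RARA"), 3L)
  expect_identical(sum(ds$manifest$label == "TTMV-RARA"), 2L)
  # bit-reproducible for a fixed master seed
  ds2 <- generate_dataset(spec)
  expect_identical(lapply(ds$samples, `[[`, "pixels"),
                   lapply(ds2$samples, `[[`, "pixels"))
  expect_identical(ds$manifest, ds2$manifest)
})

test_that("unknown class names are rejected", {
  expect_error(dataset_spec(per_class_counts = c(BCR_ABL = 3L)),
               "unknown class")
})

test_that("default spec reproduces the study's class imbalance", {
  spec <- dataset_spec()
  expect_identical(unname(spec$per_class_counts[
    c("PML-RARA", "TTMV-RARA", "NPM1-RARA", "STAT5B-RARA", "NUP98-RARG")]),
    c(509L, 98L, 58L, 38L, 12L))
})

test_that("dataset writes and reloads losslessly", {
  dir <- withr::local_tempdir()
  spec <- dataset_spec(per_class_counts = c("PML-RARA" = 2L,
                                            "NUP98-RARG" = 2L),
                       image_size = c(48, 48), master_seed = 9L)
  ds <- generate_dataset(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(file.path(dir, ds$manifest$path))))
  reloaded <- load_images(ds$manifest, dir)
  for (i in seq_along(reloaded))
    expect_identical(reloaded[[i]], ds$samples[[i]]$pixels)
})

test_that("separability scores chance for identical recipes, in [0,1] always", {
  sig <- apl_signatures()[["TTMV-RARA"]]
  twin <- sig
  twin$class_name <- "TWIN"
  same <- c(lapply(1:20, function(i) render_cell(sig, c(48, 48), seed = i)),
            lapply(1:20, function(i) {
              s <- render_cell(twin, c(48, 48), seed = 100 + i)
              s
            }))
  acc <- class_separability_check(same)
  expect_gte(acc, 0.2)
  expect_lte(acc, 0.8) # near chance for identical recipes

  # single sample per class: the value is still a valid proportion
  one_each <- lapply(seq_along(apl_signatures()), function(i)
    render_cell(apl_signatures()[[i]], c(48, 48), seed = i))
  acc1 <- class_separability_check(one_each)
  expect_gte(acc1, 0)
  expect_lte(acc1, 1)

  # a single class is undefined
  expect_error(class_separability_check(same[1:5]), "single class")
})
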