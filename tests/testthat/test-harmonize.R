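# Data model, file I/O and normalizations for communities and diets.

test_that("community tables load, normalize and round-trip", {
  v <- data.frame(name = c("A", "B"), rank = c("Genus", "Genus"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tB", "s1\t50\t50", "s2\t1\t3"), path)
  m <- load_community_table(path, vocabulary = v)
  expect_equal(unname(m["s1", ]), c(50, 50))
  expect_equal(unname(m["s2", ]), c(25, 75))

  # round trip to 1e-9
  out <- withr::local_tempfile(fileext = ".tsv")
  write_community_table(m, out)
  expect_equal(load_community_table(out, vocabulary = v), m,
    tolerance = 1e-9)

  # idempotence
  expect_equal(normalize_community(m), m)

  # degenerate all-zero row
  writeLines(c("sample_id\tA\tB", "s1\t0\t0"), path)
  expect_error(load_community_table(path, vocabulary = v), "degenerate")
})

test_that("unknown taxa are rejected unless folded into Other", {
  v <- data.frame(name = c("A", "Other"), rank = c("Genus", "Other"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tMystery", "s1\t60\t40"), path)
  expect_error(load_community_table(path, vocabulary = v), "Mystery")
  m <- load_community_table(path, vocabulary = v, fold_other = TRUE)
  expect_equal(unname(m["s1", ]), c(60, 40))
  expect_equal(colnames(m), c("A", "Other"))
})

test_that("diet normalization maps the reference span onto log2(20)..log2(80)", {
  hf <- reference_diet("HF")
  lf <- reference_diet("LF")

  # reference diets land exactly on the band ends, per nutrient
  v_hf <- build_diet_vector(hf)
  v_lf <- build_diet_vector(lf)
  hi_is_hf <- hf$value_g_per_kg >= lf$value_g_per_kg
  expect_equal(unname(v_hf[hi_is_hf]), rep(log2(80), sum(hi_is_hf)))
  expect_equal(unname(v_hf[!hi_is_hf]), rep(log2(20), sum(!hi_is_hf)))
  expect_equal(unname(v_lf[!hi_is_hf]), rep(log2(80), sum(!hi_is_hf)))
  # energy density: HF 4.7 vs LF 3.17, so HF maps to the top of the band
  expect_equal(v_hf[["Kcal/g"]], log2(80))

  # equal references map to the band midpoint
  eq <- hf
  eq$value_g_per_kg[] <- 1
  expect_equal(unname(build_diet_vector(eq, eq, eq)),
    rep(log2(50), nrow(eq)))

  # 25% blend of a nutrient with LF = 0, HF = 4: 1 g/kg -> pre-log 35
  toy <- function(x) {
    d <- data.frame(nutrient = "n", category = "fat", value_g_per_kg = x)
    class(d) <- c("diet_composition", "data.frame")
    d
  }
  blended <- blend_diets(toy(0), toy(4), 0.25)
  expect_equal(blended$value_g_per_kg, 1)
  expect_equal(unname(build_diet_vector(blended, toy(0), toy(4))), log2(35))

  # out of the extrapolated [0, 100] pre-log band
  expect_error(build_diet_vector(toy(10), toy(0), toy(4)), "band")
})

test_that("diet blending is a convex per-nutrient combination", {
  hf <- reference_diet("HF")
  lf <- reference_diet("LF")
  expect_equal(blend_diets(lf, hf, 0), lf)
  expect_equal(blend_diets(lf, hf, 1)$value_g_per_kg, hf$value_g_per_kg)
  half <- blend_diets(lf, hf, 0.5)
  expect_equal(half$value_g_per_kg[half$nutrient == "Protein"],
    0.5 * 19.3 + 0.5 * 18)
  expect_error(blend_diets(lf, hf, 1.2), "fraction")
})

test_that("log2 community transform applies the pseudocount", {
  expect_equal(log2_community(100, 0.01), log2(100.01))
  expect_equal(log2_community(0, 1), 0)
  x <- c(0, 1, 5, 50)
  expect_true(all(diff(log2_community(x)) > 0))
  expect_error(log2_community(10, 0), "pseudocount")
  expect_error(log2_community(10, -1), "pseudocount")
})

test_that("built-in fixtures have the documented composition", {
  v <- taxon_vocabulary()
  expect_equal(nrow(v), 20)
  expect_equal(anyDuplicated(v$name), 0)
  expect_equal(sum(v$rank == "Order"), 4)
  expect_equal(sum(v$rank == "Genus"), 15)
  expect_equal(sum(v$rank == "Other"), 1)

  hf <- reference_diet("HF")
  lf <- reference_diet("LF")
  expect_equal(nrow(hf), 48)
  expect_identical(hf$nutrient, lf$nutrient)
  counts <- table(hf$category)
  expect_equal(unname(counts[c("protein/amino acid", "carbohydrate", "fat",
    "mineral", "vitamin", "energy")]), c(17, 7, 4, 8, 11, 1),
    ignore_attr = TRUE)
  # spot-check cells
  val <- function(d, n) d$value_g_per_kg[d$nutrient == n]
  expect_equal(c(val(hf, "Protein"), val(lf, "Protein")), c(19.3, 18))
  expect_equal(c(val(hf, "Kcal/g"), val(lf, "Kcal/g")), c(4.7, 3.17))
  expect_equal(c(val(hf, "Magnesium_2 (sic)"), val(lf, "Magnesium_2 (sic)")),
    c(0.002709, 0.016))
  expect_equal(c(val(hf, "Fiber (cellulose)"), val(lf, "Fiber (cellulose)")),
    c(5, 15))
  expect_equal(hf$category[hf$nutrient == "Fiber (cellulose)"], "carbohydrate")
})

test_that("fixture export writes loadable TSVs", {
  dir <- withr::local_tempdir()
  paths <- export_fixtures(dir)
  d <- load_diet_table(paths[["diet_hf"]])
  expect_equal(d$value_g_per_kg, reference_diet("HF")$value_g_per_kg)
})
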