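# Signature extraction, ortholog translation, universe restriction.

test_that("extract_signature applies thresholds as documented", {
  de <- toy_de()
  sig <- extract_signature(de, lfc_min = 1, q_max = 0.05, min_size = 1)
  expect_identical(sig$up, "gA")
  expect_identical(sig$down, "gB")

  sig2 <- extract_signature(de, lfc_min = 1, q_max = 0.25, min_size = 1)
  expect_identical(sig2$up, c("gA", "gD"))
  expect_identical(sig2$down, "gB")

  expect_error(extract_signature(de, lfc_min = 1, q_max = 0.05, min_size = 5),
               "signature too small.*toy")
})

test_that("extract_signature truncates to max_size by |log2fc| with id ties", {
  de <- de_table(data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    log2fc = c(3, -3, 2, 2, 1.5),
    p_adj = rep(0.01, 5)
  ), "trunc")
  sig <- extract_signature(de, lfc_min = 1, q_max = 0.05, min_size = 1,
                           max_size = 3)
  # keeps g1, g2 (|lfc| = 3) and g3 (tie with g4 broken by id)
  expect_identical(sig$up, c("g1", "g3"))
  expect_identical(sig$down, "g2")
})

test_that("extraction is idempotent under re-application", {
  de <- toy_de()
  sig <- extract_signature(de, lfc_min = 1, q_max = 0.25, min_size = 1)
  again <- extract_signature(de, lfc_min = 1, q_max = 0.25, min_size = 1)
  expect_identical(sig, again)
})

test_that("translation follows the one-to-many policy", {
  sig <- signature("s", up = "zfA", down = character(0))
  expect_identical(
    translate_signature(sig, toy_map(list(c("zfA", "huA"))))$up, "huA")

  map2 <- toy_map(list(c("zfA", "huA"), c("zfA", "huB")))
  expect_setequal(translate_signature(sig, map2, "expand")$up,
                  c("huA", "huB"))
  expect_error(translate_signature(sig, map2, "drop_ambiguous"),
               "untranslatable")
  expect_identical(translate_signature(sig, map2, "first")$up, "huA")
})

test_that("direction conflicts are removed from both sets", {
  sig <- signature("s", up = "zfA", down = "zfB")
  map <- toy_map(list(c("zfA", "huX"), c("zfB", "huX")))
  expect_error(translate_signature(sig, map, "expand"), "untranslatable")

  # conflict removal reported when other genes survive
  sig2 <- signature("s", up = c("zfA", "zfC"), down = "zfB")
  map2 <- toy_map(list(c("zfA", "huX"), c("zfB", "huX"), c("zfC", "huC")))
  tr <- translate_signature(sig2, map2, "expand")
  expect_identical(tr$up, "huC")
  expect_length(tr$down, 0)
  expect_identical(attr(tr, "conflicts"), "huX")
})

test_that("unmapped genes are dropped silently", {
  sig <- signature("s", up = c("zfA", "zfZ"), down = character(0))
  tr <- translate_signature(sig, toy_map(list(c("zfA", "huA"))))
  expect_identical(tr$up, "huA")
})

test_that("restriction intersects with the universe and reports counts", {
  sig <- signature("s", up = c("a", "b"), down = "d")
  r <- restrict_to_universe(sig, c("a", "c", "d"))
  expect_identical(r$up, "a")
  expect_identical(r$down, "d")
  expect_identical(attr(r, "k_up"), 1L)
  expect_identical(attr(r, "k_down"), 1L)

  r2 <- restrict_to_universe(sig, c("a", "b", "d", "extra"))
  expect_identical(r2$up, sig$up)
  expect_identical(r2$down, sig$down)

  expect_error(restrict_to_universe(sig, c("x", "y")), "disjoint")
})

test_that("translate-then-restrict commutes with restricting afterwards", {
  set.seed(9)
  src <- sprintf("zf%02d", 1:30)
  map <- simulate_ortholog_map(src, frac_one_to_many = 0.2,
                               frac_unmapped = 0.1, seed = 3)
  sig <- signature("s", up = src[1:10], down = src[11:20])
  universe <- sample(unique(map$target_gene),
                     round(0.7 * length(unique(map$target_gene))))
  a <- restrict_to_universe(translate_signature(sig, map), universe)
  b <- restrict_to_universe(
    translate_signature(sig, map),
    intersect(unique(map$target_gene), universe)
  )
  expect_identical(a$up, b$up)
  expect_identical(a$down, b$down)
})

test_that("up/down disjointness is enforced by construction", {
  expect_error(signature("s", up = c("a", "b"), down = c("b", "c")),
               "overlap")
  expect_error(signature("s", character(0), character(0)), "empty")
})

test_that("panels round-trip through GMT", {
  panel <- signature_panel(list(
    signature("s1", up = c("a", "b"), down = "c", contrast_label = "t1"),
    signature("s2", up = "d", down = character(0), contrast_label = "t2")
  ))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(panel_to_gmt(panel), path)
  back <- gmt_to_panel(read_gmt(path))
  expect_identical(names(back), names(panel))
  for (nm in names(panel)) {
    expect_identical(back[[nm]]$up, panel[[nm]]$up)
    expect_identical(back[[nm]]$down, panel[[nm]]$down)
    expect_identical(back[[nm]]$contrast_label, panel[[nm]]$contrast_label)
  }
})
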