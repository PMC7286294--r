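make_ratio_reps <- function(map, values_list) {
  lapply(seq_along(values_list), function(i)
    profile_on(values_list[[i]], map,
               meta = sample_meta(paste0("r", i), replicate = i)))
}

test_that("replicate-wise subtraction", {
  map <- uniform_map(4, L = 100)
  a <- make_ratio_reps(map, list(c(1, 1, 1, 1), c(2, 2, 2, 2)))
  b <- make_ratio_reps(map, list(c(0.3, 0.3, 0.3, 0.3), c(1, 1, 1, 1)))
  d <- subtract_profiles(a, b)
  expect_length(d, 2L)
  expect_equal(d[[1]]$values, rep(0.7, 4))
  expect_equal(d[[2]]$values, rep(1, 4))
  expect_equal(subtract_profiles(a, a)[[1]]$values, rep(0, 4))
  expect_error(subtract_profiles(a, b[1]), "mismatch")
  expect_error(subtract_profiles(list(), list()), "empty")
})

test_that("differential genes apply the numerator-bound filter", {
  map <- uniform_map(30, L = 100)
  starts <- seq(0, 2500, 500)
  ann <- toy_annotation(cbind(starts, starts + 400))
  set.seed(21)
  ## plant a big difference on gene 1 (fragments 1-4)
  mk <- function() { v <- rnorm(30, 0, 0.1); v[1:4] <- v[1:4] + 3; v }
  diffs <- make_ratio_reps(map, list(mk(), mk(), mk()))

  bound_all <- data.frame(gene_id = sprintf("g%02d", 1:6),
                          transcript_id = sprintf("t%02d", 1:6),
                          score = 1, fdr = 0, bound = TRUE)
  dg <- differential_genes(diffs, ann, bound_all,
                           call_params(permutations = 50, seed = 2))
  expect_true(dg$enriched[dg$gene_id == "g01"])

  ## same gene not bound in numerator -> excluded despite significance
  bound_none <- transform(bound_all, bound = FALSE)
  dg2 <- differential_genes(diffs, ann, bound_none,
                            call_params(permutations = 50, seed = 2))
  expect_true(dg2$significant[dg2$gene_id == "g01"])
  expect_false(any(dg2$enriched))

  ## self-comparison yields nothing
  zero <- make_ratio_reps(map, list(rep(0, 30), rep(0, 30), rep(0, 30)))
  dg3 <- differential_genes(zero, ann, bound_all,
                            call_params(permutations = 50, seed = 2))
  expect_equal(sum(dg3$enriched), 0L)
})

## hand-built differential tables for the set logic
fake_diff <- function(enriched_genes, universe = sprintf("g%02d", 1:10)) {
  data.frame(gene_id = universe,
             significant = universe %in% enriched_genes,
             enriched = universe %in% enriched_genes,
             stringsAsFactors = FALSE)
}
fake_calls <- function(bound_genes, universe = sprintf("g%02d", 1:10)) {
  data.frame(gene_id = universe, bound = universe %in% bound_genes,
             stringsAsFactors = FALSE)
}

test_that("unique sets implement the two-comparison intersection rule", {
  types <- c("X", "Y", "Z")
  pw <- list(
    X_vs_Y = fake_diff(c("g01", "g02")),
    X_vs_Z = fake_diff(c("g01", "g03")),
    Y_vs_X = fake_diff(c("g04")),
    Z_vs_X = fake_diff(c("g04", "g05")),
    Y_vs_Z = fake_diff(character(0)),
    Z_vs_Y = fake_diff(character(0)))
  bounds <- list(X = fake_calls(c("g01", "g02", "g03")),
                 Y = fake_calls(c("g04")),
                 Z = fake_calls(c("g04", "g05")))
  us <- unique_sets(pw, bounds, types)

  ## g01 enriched in X vs both others; g02/g03 in only one comparison
  expect_equal(us$X$enriched, "g01")
  ## g04 enriched in Y vs X and Z vs X, bound in both Y and Z
  expect_equal(us$X$depleted, "g04")
  expect_equal(us$Y$enriched, character(0))

  ## dropping the boundness of g04 in Y removes the depletion call
  bounds$Y <- fake_calls(character(0))
  expect_equal(unique_sets(pw, bounds, types)$X$depleted, character(0))

  expect_error(unique_sets(pw[-1], bounds, types), "missing comparison")
})

test_that("unique sets are structurally disjoint", {
  ## enriched(X) uses X_vs_Y; enriched(Y) uses Y_vs_X; with consistent
  ## pairwise tables a gene cannot be uniquely enriched in two types
  types <- c("X", "Y", "Z")
  pw <- list(
    X_vs_Y = fake_diff(c("g01")), X_vs_Z = fake_diff(c("g01")),
    Y_vs_X = fake_diff(c("g02")), Y_vs_Z = fake_diff(c("g02")),
    Z_vs_X = fake_diff(c("g03")), Z_vs_Y = fake_diff(c("g03")))
  bounds <- list(X = fake_calls("g01"), Y = fake_calls("g02"),
                 Z = fake_calls("g03"))
  us <- unique_sets(pw, bounds, types)
  enr <- lapply(us, `[[`, "enriched")
  expect_equal(length(Reduce(intersect, enr)), 0L)
  for (ty in types) {
    expect_length(intersect(us[[ty]]$enriched, us[[ty]]$depleted), 0L)
  }
})

test_that("gene-class filtering", {
  cm <- c(g1 = "TF", g2 = "other", g3 = "miRNA")
  expect_equal(filter_gene_class(c("g1", "g2"), cm, "TF"), "g1")
  expect_equal(filter_gene_class(c("g1", "g2"), character(0), "TF"),
               character(0))
  expect_equal(filter_gene_class(c("g3", "g1"), cm, "miRNA"), "g3")
  ## unknown genes are class "other"
  expect_equal(filter_gene_class(c("gX", "g1"), cm, "other"), "gX")
})

test_that("transition table tracks states across stages", {
  us1 <- structure(list(
    chol = list(enriched = c("kn", "Dll"), depleted = character(0)),
    gaba = list(enriched = character(0), depleted = "x1")),
    class = "unique_sets")
  us2 <- structure(list(
    chol = list(enriched = "kn", depleted = character(0)),
    gaba = list(enriched = "Dll", depleted = character(0))),
    class = "unique_sets")
  tt <- transition_table(list(larva = us1, adult = us2))

  states <- tt$states
  ## the Dll-like switch: cholinergic enriched -> GABAergic enriched
  expect_equal(states$larva[states$gene_id == "Dll"], "enriched:chol")
  expect_equal(states$adult[states$gene_id == "Dll"], "enriched:gaba")
  expect_equal(states$adult[states$gene_id == "x1"], "none")

  ## transition counts conserve the tracked-gene count
  expect_equal(sum(tt$transitions$n), nrow(states))

  expect_error(transition_table(list(larva = us1)), ">= 2 stages")
})
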