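test_that("correlation distance matches hand-computed Pearson values", {
  x <- c(1, 2, 3)
  y <- c(1, 2, 4)
  prof <- rbind(a = x, b = y, c = -x + 10)
  colnames(prof) <- paste0("S", 1:3)
  d <- correlation_distance(prof)
  # r(a, b) = 3 / sqrt(2 * 14/3), frozen from the closed form
  r_ab <- 3 / sqrt(2 * 14 / 3)
  expect_equal(d["a", "b"], 1 - r_ab)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["a", "c"], 2)  # perfectly anti-correlated
  prof_flat <- rbind(a = x, flat = c(5, 5, 5))
  colnames(prof_flat) <- paste0("S", 1:3)
  expect_error(correlation_distance(prof_flat), "flat")
})

test_that("average linkage reproduces the hand-worked UPGMA merge order", {
  d <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- average_linkage(d)
  expect_equal(hc$height, c(1, 4))
  sets <- caflncnet:::.node_members(hc)
  expect_identical(sets[[1]], c("A", "B"))
  expect_identical(sets[[2]], c("A", "B", "C"))
  expect_true(all(diff(hc$height) >= 0))

  # two leaves: a single merge
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_length(average_linkage(d2)$height, 1)

  # label invariance: permuting rows leaves the member-set hierarchy alone
  set.seed(1)
  prof <- matrix(rnorm(6 * 12), 6, 12,
                 dimnames = list(paste0("T", 1:6), paste0("S", 1:12)))
  s1 <- caflncnet:::.node_members(average_linkage(correlation_distance(prof)))
  perm <- sample(6)
  s2 <- caflncnet:::.node_members(
    average_linkage(correlation_distance(prof[perm, ])))
  expect_setequal(caflncnet:::.node_keys(s1), caflncnet:::.node_keys(s2))
})

test_that("the root is recovered in every replicate and has AU 1", {
  set.seed(2)
  prof <- matrix(rnorm(5 * 10), 5, 10,
                 dimnames = list(paste0("T", 1:5), paste0("S", 1:10)))
  tree <- multiscale_bootstrap(prof, scales = c(0.7, 1, 1.3), n_boot = 30,
                               seed = 1)
  root <- which.max(tree$nodes$size)
  expect_true(all(tree$bp[root, ] == 1))
  expect_equal(tree$nodes$au[root], 1)
  expect_true(all(tree$bp >= 0 & tree$bp <= 1))
  # bp denominators are exact: counts are multiples of 1/n_boot
  expect_true(all(abs(tree$bp * 30 - round(tree$bp * 30)) < 1e-9))
})

test_that("a single scale reduces AU to the classical bootstrap probability", {
  set.seed(3)
  prof <- matrix(rnorm(6 * 12), 6, 12,
                 dimnames = list(paste0("T", 1:6), paste0("S", 1:12)))
  tree <- multiscale_bootstrap(prof, scales = 1, n_boot = 100, seed = 4)
  interior <- tree$nodes$bp_raw > 0.01 & tree$nodes$bp_raw < 0.99
  expect_true(any(interior))
  expect_equal(tree$nodes$au[interior], tree$nodes$bp_raw[interior],
               tolerance = 1e-10)
})

test_that("planted correlated blocks earn high AU support, decoys do not", {
  # smaller version of the recovery experiment: two 6-member blocks with
  # within-block correlation about 0.9 among 8 uncorrelated decoys
  set.seed(5)
  n <- 40
  mk_block <- function(sz, label) {
    f <- rnorm(n, sd = 1.5)
    out <- t(vapply(seq_len(sz), function(i) f + rnorm(n, sd = 0.5),
                    numeric(n)))
    rownames(out) <- paste0(label, seq_len(sz))
    out
  }
  prof <- rbind(mk_block(6, "A"), mk_block(6, "B"),
                matrix(rnorm(8 * n, sd = 0.5), 8, n,
                       dimnames = list(paste0("D", 1:8), NULL)))
  colnames(prof) <- paste0("S", 1:n)
  tree <- multiscale_bootstrap(prof, scales = seq(0.6, 1.4, 0.2),
                               n_boot = 100, seed = 1)
  keys <- caflncnet:::.node_keys(tree$members)
  au_a <- tree$nodes$au[match(paste(paste0("A", 1:6), collapse = "\x1f"), keys)]
  au_b <- tree$nodes$au[match(paste(paste0("B", 1:6), collapse = "\x1f"), keys)]
  expect_gt(au_a, 0.9)
  expect_gt(au_b, 0.9)
  decoy_only <- vapply(tree$members, function(m) all(grepl("^D", m)), logical(1))
  expect_true(all(tree$nodes$au[decoy_only & tree$nodes$size >= 4] <= 0.9))

  # seeded determinism of the whole bootstrap
  tree2 <- multiscale_bootstrap(prof, scales = seq(0.6, 1.4, 0.2),
                                n_boot = 100, seed = 1)
  expect_identical(tree$bp, tree2$bp)
  expect_identical(tree$nodes$au, tree2$nodes$au)
})

test_that("module extraction thresholds, nesting and predominance follow the rules", {
  # hand-built annotated dendrogram: 8 leaves, controlled AU values
  leaves <- paste0("T", 1:8)
  members <- list(
    c("T1", "T2"), c("T1", "T2", "T3"),          # nested, both significant
    c("T4", "T5"),                                # significant, disjoint
    c("T6", "T7"),                                # not significant
    c("T4", "T5", "T6", "T7", "T8"),              # not significant
    leaves                                        # root
  )
  members <- lapply(members, sort)
  fake <- structure(list(
    hclust = NULL, members = members,
    nodes = data.frame(node = 1:6, size = lengths(members),
                       au = c(0.97, 0.99, 0.96, 0.94, 0.5, 1),
                       bp_raw = NA, v = NA, c = NA, fit_ok = TRUE),
    bp = NULL, scales = c(0.5, 1), n_boot = 100),
    class = "annotated_dendrogram")
  mods <- extract_modules(fake, tf = "TFX", alpha = 0.05)
  # outermost significant nodes: {T1,T2,T3} (its nested child dropped) and {T4,T5}
  expect_identical(nrow(mods), 2L)
  expect_setequal(mods$members[[which(mods$size == 3)]], c("T1", "T2", "T3"))
  expect_setequal(mods$members[[which(mods$size == 2)]], c("T4", "T5"))
  # au = 0.94 is excluded at alpha 0.05; the root never becomes a module
  expect_false(any(vapply(mods$members, identical, logical(1), sort(leaves))))
  # predominant = largest
  expect_true(mods$predominant[mods$size == 3])
  expect_false(mods$predominant[mods$size == 2])
  expect_true(all(mods$cluster_p < 0.05))

  # no significant node: empty result
  fake$nodes$au <- c(0.5, 0.6, 0.7, 0.2, 0.1, 1)
  expect_identical(nrow(extract_modules(fake, tf = "TFX")), 0L)
})

test_that("annotated dendrograms round-trip to Newick with AU labels", {
  set.seed(6)
  prof <- matrix(rnorm(5 * 10), 5, 10,
                 dimnames = list(paste0("T", 1:5), paste0("S", 1:10)))
  tree <- multiscale_bootstrap(prof, scales = c(0.8, 1, 1.2), n_boot = 20,
                               seed = 1)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_annotated_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, paste0("T", 1:5))
  expect_true(all(grepl("^au=", phy$node.label)))
})
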