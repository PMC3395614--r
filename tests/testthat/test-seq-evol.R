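test_that("codon alignment translation handles codons, gaps, and stops", {
  expect_equal(translate_codon_alignment("ATG"), "M")
  expect_equal(translate_codon_alignment("ATGGCT"), "MA")
  expect_equal(translate_codon_alignment("ATG---GCT"), "M-A")
  # terminal stop is stripped, internal stop is a located error
  expect_equal(translate_codon_alignment("ATGTTTTAA"), "MF")
  expect_error(translate_codon_alignment("ATGTAATTT"),
               class = "orevo_stop_codon_error", regexp = "codon 2")
  expect_error(translate_codon_alignment("ATGG--CTT"),
               class = "orevo_alignment_error", regexp = "partial")
  expect_error(translate_codon_alignment("ATGGC"),
               class = "orevo_alignment_error")
})

test_that("coding_pair validates lengths and trims a shared terminal stop", {
  p <- coding_pair("ATGTTTTAA", "ATGTTCTAA")
  expect_equal(nchar(p$nt_a), 6)
  expect_equal(p$aa_a, "MF")
  expect_error(coding_pair("ATGGCT", "ATG"), class = "orevo_alignment_error")
})

test_that("Jukes-Cantor distance matches the closed form and its domain", {
  ident <- coding_pair(strrep("ATG", 100), strrep("ATG", 100))
  expect_equal(jukes_cantor_distance(ident), 0)
  # 12 sites, 3 mismatches: p = 0.25
  p2 <- coding_pair("AAATTTGGGCCC", "AAATTTGGGAAA")
  expect_equal(jukes_cantor_distance(p2), oracle_jc(0.25), tolerance = 1e-12)
  expect_equal(round(jukes_cantor_distance(p2), 4), 0.3041)
  # saturation: 4th-codon-position heavy divergence
  sat <- coding_pair("ATGAAA", "ATGTTT")  # 3/6 = 0.5 < 3/4 fine
  expect_silent(jukes_cantor_distance(sat))
  sat2 <- coding_pair("AAATTT", "TTTCCC")
  expect_error(jukes_cantor_distance(sat2), class = "orevo_saturation_error")
})

test_that("Jukes-Cantor distance is symmetric and increasing in p", {
  base <- "ATGGCTTGCACT"
  mut <- c("ATGGCTTGCACA", "ATGGCATGTACT")
  for (m in mut) {
    ab <- jukes_cantor_distance(coding_pair(base, m))
    ba <- jukes_cantor_distance(coding_pair(m, base))
    expect_identical(ab, ba)
  }
  p_grid <- seq(0.05, 0.70, by = 0.05)
  d <- vapply(p_grid, oracle_jc, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_true(all(d[-1] > p_grid[-1]))  # correction exceeds raw proportion
})

test_that("Grantham matrix reproduces the published scale", {
  g <- grantham_matrix()
  expect_true(isSymmetric(g))
  expect_true(all(diag(g) == 0))
  expect_true(all(g >= 0))
  m <- mean(g[upper.tri(g)])
  expect_gte(m, 99)
  expect_lte(m, 101)
  # spot values from the published matrix (rounded there to integers)
  expect_equal(g["S", "L"], 145, tolerance = 0.01)
  expect_equal(g["L", "I"], 5, tolerance = 0.2)
  expect_equal(g["C", "W"], 215, tolerance = 0.01)
})

test_that("Grantham sequence distance is a mean over compared positions", {
  tab <- grantham_matrix()
  p <- coding_pair("TCTCTT", "CTTCTT")  # S/L then L/L
  expect_equal(grantham_distance(p), tab["S", "L"] / 2)
  expect_equal(grantham_distance(p, positions = residue_positions(1)),
               tab["S", "L"])
  expect_equal(grantham_distance(p, positions = residue_positions(2)), 0)
  # zero iff identical at compared positions
  ident <- coding_pair("ATGGCTTGC", "ATGGCTTGC")
  expect_identical(grantham_distance(ident), 0)
  # symmetric
  expect_equal(grantham_distance(coding_pair("TCT", "CTT")),
               grantham_distance(coding_pair("CTT", "TCT")))
  # gapped-out positions are errors when nothing remains
  gap <- coding_pair("---GCT", "ATG---")
  expect_error(grantham_distance(gap), class = "orevo_no_sites_error")
  expect_error(grantham_distance(p, positions = residue_positions(c(1, 9))),
               class = "orevo_position_error")
})

test_that("NG86 degenerate cases behave as the counting rules force", {
  ident <- coding_pair(strrep("ATGGCT", 10), strrep("ATGGCT", 10))
  r <- nei_gojobori_omega(ident)
  expect_equal(r$Sd + r$Nd, 0)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_false(r$omega_defined)
  # one synonymous third-position change in six codons: dN = 0, omega = 0
  a <- "ATGGCTTGCACTGGACTT"
  b <- "ATGGCATGCACTGGACTT"
  r2 <- nei_gojobori_omega(coding_pair(a, b))
  expect_equal(r2$Nd, 0)
  expect_equal(r2$dN, 0)
  expect_gt(r2$dS, 0)
  expect_true(r2$omega_defined)
  expect_equal(r2$omega, 0)
  # nonsynonymous-only divergence: dS = 0, omega undefined
  r3 <- nei_gojobori_omega(coding_pair("ATGGCT", "ATGTCT"))
  expect_equal(r3$Sd, 0)
  expect_equal(r3$dS, 0)
  expect_false(r3$omega_defined)
})

test_that("NG86 counts match exhaustive pathway enumeration on toys", {
  # two-nucleotide codon difference resolved over both pathways
  cases <- list(c("TTT", "GTA"), c("ATG", "ACG"), c("TGC", "TAT"),
                c("CCT", "CAG"), c("ATGTTT", "ATGCTC"))
  for (cs in cases) {
    pr <- coding_pair(cs[1], cs[2])
    got <- nei_gojobori_omega(pr)
    ca <- substring(cs[1], seq(1, nchar(cs[1]), 3), seq(3, nchar(cs[1]), 3))
    cb <- substring(cs[2], seq(1, nchar(cs[2]), 3), seq(3, nchar(cs[2]), 3))
    exp_sites_a <- sum(vapply(ca, oracle_syn_sites, numeric(1)))
    exp_sites_b <- sum(vapply(cb, oracle_syn_sites, numeric(1)))
    diffs <- mapply(oracle_codon_diffs, ca, cb)
    expect_equal(got$S, (exp_sites_a + exp_sites_b) / 2)
    expect_equal(got$S + got$N, 3 * length(ca))
    expect_equal(got$Sd, sum(diffs[1, ]))
    expect_equal(got$Nd, sum(diffs[2, ]))
  }
})

test_that("gap codons are excluded pairwise from every metric", {
  p <- coding_pair("ATG---TGCACT", "ATGGCTTGC---")
  r <- nei_gojobori_omega(p)
  expect_equal(r$n_codons, 2)
  expect_equal(r$S + r$N, 6)
  expect_equal(jukes_cantor_distance(p), 0)
})

test_that("neighbor joining recovers trees from additive distances", {
  # two taxa: the single connecting edge carries the full distance
  dm2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining_tree(dm2)
  expect_equal(sum(t2$edge.length), 0.5)
  # three taxa: closed-form star branch lengths
  d_ab <- 0.3; d_ac <- 0.5; d_bc <- 0.6
  dm3 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dm3["A", "B"] <- dm3["B", "A"] <- d_ab
  dm3["A", "C"] <- dm3["C", "A"] <- d_ac
  dm3["B", "C"] <- dm3["C", "B"] <- d_bc
  t3 <- neighbor_joining_tree(dm3)
  tip_edge <- t3$edge[, 2] <= 3
  bl <- numeric(3)
  bl[t3$edge[tip_edge, 2]] <- t3$edge.length[tip_edge]
  names(bl) <- t3$tip.label
  expect_equal(unname(bl["A"]), (d_ab + d_ac - d_bc) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["B"]), (d_ab + d_bc - d_ac) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["C"]), (d_ac + d_bc - d_ab) / 2, tolerance = 1e-9)
  # additive four-taxon matrix: round trip through cophenetic distances
  for (seed in 1:5) {
    ref <- withr::with_seed(seed, ape::rtree(8))
    dm <- ape::cophenetic.phylo(ref)
    est <- neighbor_joining_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)],
                 dm, tolerance = 1e-8)
  }
  # invalid inputs
  bad <- dm2; bad[1, 2] <- 0.4
  expect_error(neighbor_joining_tree(bad), class = "orevo_distance_error")
  neg <- dm2; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(neighbor_joining_tree(neg), class = "orevo_distance_error")
})

test_that("pairwise_metrics builds the per-pair table and flags saturation", {
  aln <- c(h = "ATGGCTTGCACT", c = "ATGGCATGCACT", m = "ATGGCTTGCACA")
  tbl <- pairwise_metrics(aln)
  expect_equal(nrow(tbl), 3)
  expect_named(tbl, c("id_a", "id_b", "jc", "grantham_orf", "grantham_22aa",
                      "dn", "ds", "omega"))
  hc <- tbl[tbl$id_a == "h" & tbl$id_b == "c", ]
  expect_equal(hc$grantham_orf, 0)  # synonymous difference only
  expect_gt(hc$ds, 0)
  expect_error(
    pairwise_metrics(aln, pairs = data.frame(id_a = "h", id_b = "zzz")),
    class = "orevo_alignment_error", regexp = "zzz")
})
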