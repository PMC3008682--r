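make_taxa <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(family = r[1], genus = r[2], species = r[3], site = r[4],
               stringsAsFactors = FALSE)))
}

test_that("grafting builds genus and species-site polytomies within families", {
  bb <- suppressWarnings(read_newick("(Fam1,Fam2)root;"))
  taxa <- make_taxa(c("Fam1", "G1", "s1", "A"),
                    c("Fam1", "G2", "s2", "A"),
                    c("Fam2", "G3", "s3", "A"))
  gt <- graft_taxa(bb, taxa)
  expect_equal(ape::Ntip(gt), 3L)
  expect_setequal(gt$tip.label, c("G1_s1@A", "G2_s2@A", "G3_s3@A"))
  # Fam1 node has the two genus lineages as children
  fam1 <- which(gt$node.label == "Fam1") + ape::Ntip(gt)
  expect_length(fam1, 1L)
  kids <- gt$edge[gt$edge[, 1] == fam1, 2]
  expect_length(kids, 2L)
})

test_that("a species at several sites becomes sibling tips under one node", {
  bb <- suppressWarnings(read_newick("(Fam1,Fam2)root;"))
  taxa <- make_taxa(c("Fam1", "G1", "s1", "A"),
                    c("Fam1", "G1", "s1", "B"),
                    c("Fam2", "G2", "s2", "A"))
  gt <- graft_taxa(bb, taxa)
  expect_setequal(gt$tip.label, c("G1_s1@A", "G1_s1@B", "G2_s2@A"))
  sp <- which(gt$node.label == "G1_s1") + ape::Ntip(gt)
  kids <- gt$edge[gt$edge[, 1] == sp, 2]
  expect_setequal(gt$tip.label[kids], c("G1_s1@A", "G1_s1@B"))
  expect_equal(attr(gt, "species_nodes"), "G1_s1")
})

test_that("single-member chains collapse and unsampled families are pruned", {
  bb <- suppressWarnings(read_newick("((Fam1,Fam2),Fam3)root;"))
  taxa <- make_taxa(c("Fam1", "G1", "s1", "A"),
                    c("Fam3", "G3", "s3", "A"),
                    c("Fam3", "G3", "s4", "A"))
  gt <- graft_taxa(bb, taxa)  # Fam2 unsampled
  expect_equal(ape::Ntip(gt), 3L)
  expect_setequal(gt$tip.label, c("G1_s1@A", "G3_s3@A", "G3_s4@A"))
  # Fam1 collapsed to a single tip lineage: no Fam1/G1 internal nodes left
  expect_false(any(c("Fam1", "G1") %in% gt$node.label))
})

test_that("unplaced families raise an error listing the offenders", {
  bb <- suppressWarnings(read_newick("(Fam1,Fam2)root;"))
  taxa <- make_taxa(c("FamX", "G1", "s1", "A"),
                    c("Fam1", "G2", "s2", "A"))
  expect_error(graft_taxa(bb, taxa), "FamX")
})

test_that("duplicate species-site records are rejected", {
  expect_error(validate_taxa(make_taxa(c("F", "G", "s", "A"),
                                       c("F", "G", "s", "A"))),
               "duplicate")
})

test_that("even-spacing dating: midpoints, thirds, and the max-candidate rule", {
  # single undated node between root (100) and tips: midpoint 50
  t1 <- suppressWarnings(read_newick("((A,B)u,C)root;"))
  s1 <- smooth_ages(t1, c(root = 100))
  ages <- attr(s1, "node_ages")
  expect_equal(ages[ape::Ntip(t1) + which(t1$node.label == "u")], 50)

  # chain dated(90) -> u1 -> u2 -> tips: thirds 60, 30
  t2 <- suppressWarnings(read_newick("(((A,B)u2,C)u1,D)r;"))
  s2 <- smooth_ages(t2, c(r = 90))
  a2 <- attr(s2, "node_ages")
  nl <- function(tr, nm) ape::Ntip(tr) + which(tr$node.label == nm)
  expect_equal(unname(a2[nl(t2, "u1")]), 60)
  expect_equal(unname(a2[nl(t2, "u2")]), 30)

  # dated(100) -> u -> {dated 40, tip}: the dated-descendant path gives the
  # larger candidate (70 vs 50) and is chosen
  t3 <- suppressWarnings(read_newick("(((X,Y)d40,W)u,Z)top;"))
  s3 <- smooth_ages(t3, c(top = 100, d40 = 40))
  a3 <- attr(s3, "node_ages")
  expect_equal(unname(a3[nl(t3, "u")]), 70)
  expect_equal(unname(a3[nl(t3, "d40")]), 40)  # dated node pinned exactly
  expect_true(is_ultrametric(s3, rel_tol = 1e-9))
})

test_that("dating errors: missing root age and dated-age inversions", {
  t1 <- suppressWarnings(read_newick("((A,B)u,C)root;"))
  expect_error(smooth_ages(t1, c(other = 10)), "root")
  t2 <- suppressWarnings(read_newick("(((X,Y)young,W)old,Z)top;"))
  expect_error(smooth_ages(t2, c(top = 100, old = 20, young = 50)),
               "inversion")
})

test_that("smooth_ages is idempotent and respects the epsilon policy", {
  bb <- suppressWarnings(read_newick("((Fam1,Fam2)cladeA,Fam3)root;"))
  taxa <- make_taxa(c("Fam1", "G1", "s1", "A"), c("Fam1", "G1", "s1", "B"),
                    c("Fam1", "G2", "s2", "A"), c("Fam2", "G3", "s3", "A"),
                    c("Fam3", "G4", "s4", "A"), c("Fam3", "G4", "s5", "A"))
  gt <- graft_taxa(bb, taxa)
  ages <- c(root = 100, cladeA = 60, Fam1 = 30)
  sm <- smooth_ages(gt, ages)
  expect_true(is_ultrametric(sm, rel_tol = 1e-9))
  expect_equal(ape::Ntip(sm), nrow(taxa))
  expect_setequal(sm$tip.label, paste0(taxa$genus, "_", taxa$species, "@", taxa$site))
  expect_true(all(sm$edge.length > 0))
  # dated nodes pinned exactly
  a <- attr(sm, "node_ages")
  nl <- function(nm) ape::Ntip(sm) + which(sm$node.label == nm)
  expect_equal(unname(a[nl("root")]), 100)
  expect_equal(unname(a[nl("cladeA")]), 60)
  expect_equal(unname(a[nl("Fam1")]), 30)
  # duplicate species-site tips separated by the epsilon terminal branches
  expect_equal(unname(a[nl("G1_s1")]), 1e-6 * 100)
  # idempotence: rerunning on the dated output changes nothing
  sm2 <- smooth_ages(sm, ages)
  expect_equal(sm2$edge.length, sm$edge.length, tolerance = 1e-12)
})
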