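# Signature derivation: list voting, DESeq2-based differential
# expression, threshold selection, intersection, ortholog mapping and
# correlation expansion.

test_that("inflammatory-universe voting keeps genes in >= min_votes lists", {
  a <- gene_list("A", c("Tnf", "Il6", "Ccl2"))
  b <- gene_list("B", c("IL6", "CCL2", "Ifit1"))
  c_ <- gene_list("C", c("ccl2", "IFIT1", "Tnf"))
  out <- assemble_inflammatory_genes(list(a, b, c_), min_votes = 2)
  expect_setequal(toupper(out), c("TNF", "IL6", "CCL2", "IFIT1"))
  # first-seen casing preserved, output sorted
  expect_identical(as.character(out), sort(as.character(out)))
  expect_true("Tnf" %in% as.character(out))
  # a gene in one list only is excluded
  d <- gene_list("D", c("Unique1", "Tnf"))
  out2 <- assemble_inflammatory_genes(list(a, d), min_votes = 2)
  expect_false("UNIQUE1" %in% toupper(out2))
  expect_error(assemble_inflammatory_genes(list(a), min_votes = 2),
               "fewer lists")
})

test_that("voting is invariant to list order and within-list duplicates", {
  a <- gene_list("A", c("TNF", "IL6"))
  b <- gene_list("B", c("il6", "il6", "CXCL1"))
  c_ <- gene_list("C", c("CXCL1", "TNF"))
  o1 <- assemble_inflammatory_genes(list(a, b, c_))
  o2 <- assemble_inflammatory_genes(list(c_, a, b))
  expect_setequal(toupper(o1), toupper(o2))
})

test_that("DE recovers a strong toy gene, cross-checked against edgeR", {
  # one real effect among null genes: counts (10,12) vs (400,380)
  set.seed(31)
  n_null <- 300
  counts <- rbind(
    HIT = c(10L, 12L, 400L, 380L),
    matrix(rnbinom(n_null * 4, mu = 100, size = 10), nrow = n_null,
           dimnames = list(sprintf("N%03d", seq_len(n_null)), NULL)))
  colnames(counts) <- c("ref_1", "ref_2", "trt_1", "trt_2")
  cond <- c("ref", "ref", "trt", "trt")
  de <- differential_expression(counts, cond, "trt", "ref")
  hit <- de[de$gene == "HIT", ]
  expect_lt(abs(hit$log2_fold - 5), 0.6)
  expect_lt(hit$adj_p, 0.01)
  expect_true("HIT" %in% as.character(select_up(de)))
  # independent oracle: edgeR exact test on the same table
  y <- edgeR::DGEList(counts = counts, group = cond)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y, pair = c("ref", "trt"))
  expect_lt(abs(et$table["HIT", "logFC"] - hit$log2_fold), 0.5)
  expect_lt(et$table["HIT", "PValue"], 1e-6)
})

test_that("DE power and construction oracle on simulated counts", {
  cfg <- sim_config(n_genes = 100, counts_n_genes = 800,
                    counts_n_reps = 5, counts_lfc = 2.5,
                    counts_de_shared = 50, counts_de_unique = 25,
                    counts_frac_down = 0.3, counts_n_inflammatory = 200,
                    seed = 17)
  sim <- simulate_counts(cfg)
  de_a <- differential_expression(sim$counts, sim$conditions, "KO_A", "WT")
  de_b <- differential_expression(sim$counts, sim$conditions, "KO_B", "WT")

  # >= 90% of embedded up-genes recovered at fold > 2 & adj_p < 0.01
  truth_a <- sim$truth$de[sim$truth$de$condition == "KO_A", ]
  up_a <- select_up(de_a)
  expect_gte(mean(truth_a$gene[truth_a$lfc > 0] %in% up_a), 0.9)

  # up and down calls never overlap
  expect_length(intersect(select_up(de_a), select_down(de_a)), 0)

  # BH step-up: adjusted p non-decreasing in p, and adj_p >= p
  ord <- order(de_a$p)
  expect_true(all(diff(de_a$adj_p[ord]) >= -1e-12))
  expect_true(all(de_a$adj_p >= de_a$p - 1e-12))

  # construction oracle: signature = shared up-DE genes in the
  # inflammatory universe, recovered through the full derivation path
  infl <- gene_list("inflammatory", sim$truth$inflammatory)
  sig <- derive_signature(select_up(de_a), select_up(de_b), infl)
  expect_setequal(as.character(sig), sim$truth$expected_up)
  down <- derive_down(select_down(de_a), select_down(de_b), infl)
  expect_setequal(as.character(down), sim$truth$expected_down)
})

test_that("fold-threshold boundaries are strict", {
  de <- data.frame(gene = c("A", "B", "C", "D"),
                   base_mean = 100,
                   log2_fold = c(1, 2, -1, -2),  # folds 2, 4, 1/2, 1/4
                   p = 1e-6, adj_p = c(1e-4, 0.5, 1e-4, 1e-4))
  expect_false("A" %in% as.character(select_up(de)))    # fold exactly 2
  expect_false("B" %in% as.character(select_up(de)))    # adj_p too high
  expect_false("C" %in% as.character(select_down(de)))  # fold exactly 1/2
  expect_identical(as.character(select_down(de)), "D")
})

test_that("DE input validation", {
  counts <- matrix(1:12, nrow = 3,
                   dimnames = list(c("a", "b", "c"),
                                   c("r1", "r2", "t1", "t2")))
  expect_error(
    differential_expression(counts, c("r", "r", "t", "t"), "t", "missing"),
    "replicates")
  counts_neg <- counts
  counts_neg[1, 1] <- -1L
  expect_error(
    differential_expression(counts_neg, c("r", "r", "t", "t"), "t", "r"),
    "negative")
  expect_error(
    differential_expression(counts, c("r", "t", "t", "t"), "t", "r"),
    "replicates")
})

test_that("derivation is case-insensitive, order-invariant, sorted", {
  infl <- gene_list("inflammatory", c("Ifitm3", "Bst2", "Tlr2", "Cd14"))
  s1 <- derive_signature(c("IFITM3", "BST2", "OTHER"),
                         c("bst2", "ifitm3", "tlr2"), infl)
  s2 <- derive_signature(c("ifitm3", "bst2", "tlr2"),
                         c("OTHER", "BST2", "IFITM3"), infl)
  expect_identical(as.character(s1), as.character(s2))
  expect_identical(as.character(s1), c("Bst2", "Ifitm3"))
  expect_length(derive_signature(c("A"), c("B"), infl), 0)
  expect_error(derive_signature(c("A"), c("A"), gene_list("e", character(0))),
               "empty")
})

test_that("ortholog mapping flips species, warns on misses, round-trips", {
  map <- data.frame(from = c("Ifitm3", "Bst2", "Tlr2"),
                    to = c("IFITM3", "BST2", "TLR2"))
  sig <- pi_signature(up = c("Ifitm3", "Bst2", "Lost1"), species = "mouse")
  expect_warning(hum <- map_orthologs(sig, map), "Lost1")
  expect_identical(hum$species, "human")
  expect_setequal(hum$up, c("IFITM3", "BST2"))
  expect_identical(hum$provenance$unmapped, "Lost1")
  back <- map_orthologs(hum, data.frame(from = map$to, to = map$from))
  expect_setequal(back$up, c("Ifitm3", "Bst2"))
  expect_identical(back$species, "mouse")
})

test_that("expand_signature recovers co-activated genes and handles
           degenerate input", {
  # cell-line-like setting (no infiltration slopes), 2000-gene universe:
  # rank competition between the coupled set and the signature stays small
  cfg <- sim_config(n_genes = 2000, n_tissues = 2,
                    n_reference_per_tissue = 50,
                    n_tumors_per_tissue = 200, n_normals_per_tissue = 30,
                    slope_zero_fraction = 1, seed = 23)
  sim <- simulate_tumor_cohort(cfg)
  tum <- names(sim$truth$latent)
  expr <- sim$expression[, tum]
  # couple 30 background genes to the PI program at activation strength
  coupled <- sprintf("BG%05d", 1:30)
  pi_on <- sim$truth$pi_status[tum]
  expr[coupled, pi_on] <- expr[coupled, pi_on] + cfg$activation_mean
  # a constant gene must come out with correlation treated as 0
  expr["BG00040", ] <- 3.14
  scores <- score_cohort(expr, sim$truth$signature)
  exp_genes <- expand_signature(expr, scores, min_corr = 0.5)
  expect_gte(mean(coupled %in% exp_genes$gene), 0.9)
  expect_false("BG00040" %in% exp_genes$gene)
  expect_true(all(exp_genes$corr > 0.5))
  expect_error(expand_signature(expr[, 1:2], scores), ">= 3 samples")
})
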