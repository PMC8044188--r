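test_that("default identity is the argmax with flagged ties", {
  groups10 <- c("LRC", "TSPT_HZS", "TSPT_C72", "M-Reid_PA", "M-Reid_Z58",
                "X", "IDT", "P", "SS", "Lan")
  q <- setNames(c(1, rep(0, 9)), groups10)
  d <- default_id(q)
  expect_equal(as.character(d), "LRC")
  expect_false(attr(d, "tie"))
  # tied maxima take the first-listed group and are flagged
  qt <- setNames(c(0.33, 0.33, 0.18, 0.16), c("IDT", "X", "M-Reid_PA", "P"))
  dt <- default_id(qt)
  expect_equal(as.character(dt), "IDT")
  expect_true(attr(dt, "tie"))
  du <- default_id(rep(0.25, 4))
  expect_equal(as.character(du), "G1")
  expect_true(attr(du, "tie"))
})

test_that("the adjusted rule follows its printed branches", {
  t <- assignment_thresholds()
  # dominant and clear
  expect_equal(as.character(adjusted_id(c(A = 1, B = 0), t)), "A")
  expect_equal(as.character(adjusted_id(c(A = 0.7, B = 0.3), t)), "A")
  # dominant but crowded: Para
  expect_equal(as.character(adjusted_id(c(A = 0.52, B = 0.45, C = 0.03),
                                        t)), "A_Para")
  # not dominant but well ahead: Para
  expect_equal(as.character(adjusted_id(c(A = 0.45, B = 0.25, C = 0.30),
                                        t)), "A_Para")
  # neither: Mixed (top value not dominant, margin under 0.15)
  expect_equal(as.character(adjusted_id(c(A = 0.45, B = 0.35, C = 0.20),
                                        t)), "Mixed")
  # exact margin of 0.1 at dominant top resolves to the clear label
  ab <- adjusted_id(c(A = 0.55, B = 0.45), t)
  expect_equal(as.character(ab), "A")
  expect_true(attr(ab, "boundary"))
})

test_that("the printed indicator rows reproduce their reported identities",
{
  # CT609: Q_LRC = 1.0 -> LRC, clearly
  q_ct609 <- c(LRC = 1, TSPT_HZS = 0, TSPT_C72 = 0)
  expect_equal(as.character(default_id(q_ct609)), "LRC")
  expect_equal(as.character(adjusted_id(q_ct609)), "LRC")
  # PHG30 (IDT 0.33, X 0.33, M-Reid_PA 0.18, rest 0.16): default IDT by
  # first-listed tie, adjusted Mixed (0.33 <= 0.5 and margin 0 < 0.15)
  q_phg30 <- c(IDT = 0.33, X = 0.33, `M-Reid_PA` = 0.18, P = 0.16)
  expect_equal(as.character(default_id(q_phg30)), "IDT")
  expect_equal(as.character(adjusted_id(q_phg30)), "Mixed")
})

test_that("assignments are equivariant under group relabeling", {
  set.seed(1)
  Q <- popstructr:::.rdirichlet(50, c(1, 1, 1))
  colnames(Q) <- c("A", "B", "C")
  rownames(Q) <- paste0("L", 1:50)
  a1 <- assign_groups(Q)
  perm <- c(3, 1, 2)
  a2 <- assign_groups(Q[, perm])
  expect_equal(a1$adjusted_id, a2$adjusted_id)
  expect_equal(a1$default_id[!a1$default_tie],
               a2$default_id[!a2$default_tie])
  # adjusted label is always built on the argmax group (or Mixed)
  expect_true(all(a1$adjusted_id == "Mixed" |
                    a1$base_group == a1$group_of_max))
})

test_that("pure-line panels are assigned to their generating groups", {
  p <- simulate_panel(sim_config(n_lines = 120, n_loci = 800,
                                 n_chromosomes = 2, K_true = 3,
                                 divergence_F = 0.3, pure_fraction = 1,
                                 seed = 3))
  fit <- fit_admixture(p$genotypes, 3, seed = 4, n_restarts = 3)
  asg <- assign_groups(fit$Q)
  mg <- match_groups(fit$Q, p$truth$true_Q)
  est_base <- sprintf("G%d", order(mg$perm)[match(asg$base_group,
                                                  colnames(fit$Q))])
  truth <- colnames(p$truth$true_Q)[max.col(p$truth$true_Q)]
  ok <- asg$adjusted_id != "Mixed" & est_base == truth
  expect_gte(mean(ok), 0.95)
})

test_that("indicator lines name the anonymous fitted groups", {
  Q <- rbind(c(0.9, 0.05, 0.05), c(0.1, 0.8, 0.1), c(0.05, 0.05, 0.9),
             c(0.85, 0.1, 0.05))
  rownames(Q) <- c("i1", "i2", "i3", "x")
  colnames(Q) <- c("G1", "G2", "G3")
  reg <- data.frame(line = c("i1", "i2", "i3"),
                    known_group = c("SS", "IDT", "TSPT"))
  nm <- name_groups_by_indicators(Q, reg)
  expect_equal(colnames(nm$Q), c("SS", "IDT", "TSPT"))
  # a column without indicator votes keeps its label
  nm2 <- name_groups_by_indicators(Q, reg[1:2, ])
  expect_equal(colnames(nm2$Q), c("SS", "IDT", "G3"))
})

test_that("indicator concordance counts Para as its base and Mixed as miss",
{
  asg <- data.frame(line = c("a", "b", "c", "d"),
                    default_id = c("X", "Y", "X", "Y"),
                    adjusted_id = c("X", "Y_Para", "Mixed", "X"),
                    base_group = c("X", "Y", "Mixed", "X"),
                    q_max = c(0.9, 0.55, 0.4, 0.8))
  reg <- data.frame(line = c("a", "b", "c", "d"),
                    known_group = c("X", "Y", "X", "Y"))
  cc <- indicator_concordance(asg, reg)
  expect_equal(cc$fraction, 0.5)  # a and b concordant, c Mixed, d wrong
  expect_error(indicator_concordance(asg,
                                     data.frame(line = "a",
                                                known_group = NA)),
               "no indicator")
  # the single discordant line alone scores zero
  cc2 <- indicator_concordance(asg[4, ], reg[4, ])
  expect_equal(cc2$fraction, 0)
})

test_that("group shares sum to one in both accounting modes", {
  asg <- data.frame(line = paste0("L", 1:10),
                    adjusted_id = c(rep("A", 4), "A_Para", rep("B", 3),
                                    "Mixed", "Mixed"),
                    base_group = c(rep("A", 5), rep("B", 3), "Mixed",
                                   "Mixed"))
  sh <- group_shares(asg, supergroups = c(A = "Super1", B = "Super2"))
  with_base <- setNames(sh$para_with_base$proportion,
                        sh$para_with_base$group)
  expect_equal(with_base[["A"]], 0.5)
  expect_equal(with_base[["B"]], 0.3)
  expect_equal(with_base[["Mixed"]], 0.2)
  expect_equal(sum(sh$para_separate$proportion), 1)
  expect_equal(sum(sh$supergroup$proportion), 1)
  # single-line panel
  one <- group_shares(asg[1, ])
  expect_equal(one$para_with_base$proportion, 1)
})
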