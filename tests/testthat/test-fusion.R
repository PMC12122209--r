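test_that("the four printed rules fire on their canonical cases", {
  # consensus P: CP=P (mu_P .9), CA=P (mu_A .2 i.e. score_P .8)
  d <- fuse_outputs(make_output("w", 0.9), make_output("w", 0.8))
  expect_equal(d$fused_label, "P"); expect_equal(d$rule_fired, "a")
  expect_equal(d$fused_score_P, 0.9)  # consensus P takes CP's score

  d <- fuse_outputs(make_output("w", 0.3), make_output("w", 0.2))
  expect_equal(d$fused_label, "A"); expect_equal(d$rule_fired, "b")
  expect_equal(d$fused_score_P, 0.2)  # consensus A takes CA's score

  # conflict, absence evidence stronger: mu_P(CP)=.60 vs mu_A(CA)=.70
  d <- fuse_outputs(make_output("w", 0.60), make_output("w", 0.30))
  expect_equal(d$fused_label, "A"); expect_equal(d$rule_fired, "c")

  # conflict, presence evidence stronger: mu_P(CP)=.80 vs mu_A(CA)=.55
  d <- fuse_outputs(make_output("w", 0.80), make_output("w", 0.45))
  expect_equal(d$fused_label, "P"); expect_equal(d$rule_fired, "d")
})

test_that("fusion matches the brute-force rule interpreter over all cases", {
  labs <- c("P", "A")
  orders <- c("<", "=", ">")
  for (tie_rule in c("prefer_P", "prefer_A")) {
    for (uncovered_rule in c("confidence_vote", "prefer_specialist")) {
      policy <- fusion_policy(tie_rule, uncovered_rule)
      for (lab_cp in labs) for (lab_ca in labs) for (ord in orders) {
        sc <- score_pair_cases(lab_cp, lab_ca, ord)
        out_cp <- make_output("w", sc$score_p_cp)
        out_ca <- make_output("w", sc$score_p_ca)
        expect_equal(out_cp$label, lab_cp)
        expect_equal(out_ca$label, lab_ca)
        got <- fuse_outputs(out_cp, out_ca, policy)
        want <- oracle_fuse_one(lab_cp, lab_ca,
                                mu_p_cp = out_cp$score_P, mu_a_ca = out_ca$score_A,
                                mu_a_cp = out_cp$score_A, mu_p_ca = out_ca$score_P,
                                tie_rule, uncovered_rule)
        info <- sprintf("CP=%s CA=%s ord=%s tie=%s unc=%s",
                        lab_cp, lab_ca, ord, tie_rule, uncovered_rule)
        expect_equal(got$fused_label, want$label, info = info)
        expect_equal(got$rule_fired, want$rule, info = info)
      }
    }
  }
})

test_that("consensus dominates regardless of scores and policy", {
  set.seed(31)
  for (i in 1:50) {
    s_cp <- runif(1)
    # force agreement by reflecting CA's score to the same side of 0.5
    s_ca <- if (s_cp >= 0.5) runif(1, 0.5, 1) else runif(1, 0, 0.4999)
    for (pol in list(fusion_policy(), fusion_policy("prefer_A", "prefer_specialist"),
                     fusion_policy(score_rule = "average"))) {
      d <- fuse_outputs(make_output("w", s_cp), make_output("w", s_ca), pol)
      expect_equal(d$fused_label, if (s_cp >= 0.5) "P" else "A")
    }
  }
})

test_that("fusing a classifier output with itself reproduces that output", {
  set.seed(17)
  out <- make_output(sprintf("s%02d", 1:40), runif(40))
  d <- fuse_outputs(out, out)
  expect_equal(d$fused_label, out$label)
  expect_equal(d$fused_score_P, out$score_P)
  expect_true(all(d$rule_fired %in% c("a", "b")))
})

test_that("every sample gets exactly one decision and rule counts sum to n", {
  set.seed(23)
  n <- 200
  out_cp <- make_output(sprintf("s%03d", 1:n), runif(n))
  out_ca <- make_output(sprintf("s%03d", 1:n), runif(n))
  d <- fuse_outputs(out_cp, out_ca)
  expect_equal(nrow(d), n)
  expect_equal(sum(table(d$rule_fired)), n)
  expect_true(all(d$rule_fired %in% c("a", "b", "c", "d", "tie", "uncovered")))
  # fused label P iff rule in {a, d} or a P-resolved open case
  expect_true(all((d$fused_label == "P") ==
                    (d$rule_fired %in% c("a", "d") |
                       (d$rule_fired %in% c("tie", "uncovered") & d$fused_label == "P"))))
})

test_that("raising CP's presence score never flips a fused P to A", {
  set.seed(41)
  for (i in 1:100) {
    s_cp <- runif(1)
    s_ca <- runif(1)
    base <- fuse_outputs(make_output("w", s_cp), make_output("w", s_ca))
    if (base$fused_label != "P") next
    # any higher CP presence score, label-consistent or crossing 0.5 upward
    s_up <- runif(1, s_cp, 1)
    bumped <- fuse_outputs(make_output("w", s_up), make_output("w", s_ca))
    expect_equal(bumped$fused_label, "P",
                 info = sprintf("s_cp %.3f -> %.3f, s_ca %.3f", s_cp, s_up, s_ca))
  }
})

test_that("mismatched sample ids are rejected naming the first mismatch", {
  a <- make_output(c("s1", "s2"), c(0.9, 0.8))
  b <- make_output(c("s1", "s3"), c(0.9, 0.8))
  expect_error(fuse_outputs(a, b), "position 2.*s2.*s3")
})

test_that("score rules and decision export behave as documented", {
  out_cp <- make_output(c("s1", "s2"), c(0.9, 0.2))
  out_ca <- make_output(c("s1", "s2"), c(0.6, 0.4))
  avg <- fuse_outputs(out_cp, out_ca, fusion_policy(score_rule = "average"))
  expect_equal(avg$fused_score_P, c((0.9 + 0.6) / 2, (0.2 + 0.4) / 2))

  path <- withr::local_tempfile(fileext = ".csv")
  write_fusion_decisions(avg, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(names(back), c("sample_id", "fused_label", "fused_score_P", "rule_fired"))
  expect_equal(back$fused_label, avg$fused_label)
})
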