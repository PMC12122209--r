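# Shared fixtures, built in code at test time.

# Two linearly separable 2-D point clouds, four points per class.
separable_view <- function() {
  pts <- rbind(
    c(2, 2), c(3, 2), c(2, 3), c(3, 3),      # P cloud
    c(-2, -2), c(-3, -2), c(-2, -3), c(-3, -3)  # A cloud
  )
  feature_view("sep", sprintf("x%d", 1:8), pts)
}

separable_labels <- c(rep("P", 4), rep("A", 4))

# Manifest with the three categories in known counts.
counts_manifest <- function(n_dys, n_no_dys, n_oscc) {
  n <- n_dys + n_no_dys + n_oscc
  as_manifest(
    sample_id = sprintf("m%04d", seq_len(n)),
    category = c(rep("leukoplakia_with_dysplasia", n_dys),
                 rep("leukoplakia_without_dysplasia", n_no_dys),
                 rep("oscc", n_oscc))
  )
}

# Hand-build classifier outputs with given labels implied by scores.
make_output <- function(ids, score_P) classifier_output(ids, score_P)

# Independent brute-force interpreter of the class-selection rules, coded
# directly from the rule statements (used as the oracle for fuse_outputs).
oracle_fuse_one <- function(lab_cp, lab_ca, mu_p_cp, mu_a_ca, mu_a_cp, mu_p_ca,
                            tie_rule, uncovered_rule) {
  if (lab_cp == "P" && lab_ca == "P") return(list(label = "P", rule = "a"))
  if (lab_cp == "A" && lab_ca == "A") return(list(label = "A", rule = "b"))
  if (lab_cp == "P" && lab_ca == "A") {
    if (mu_a_ca > mu_p_cp) return(list(label = "A", rule = "c"))
    if (mu_a_ca < mu_p_cp) return(list(label = "P", rule = "d"))
    return(list(label = if (tie_rule == "prefer_P") "P" else "A", rule = "tie"))
  }
  # CP = A, CA = P
  if (uncovered_rule == "prefer_specialist") {
    return(list(label = "A", rule = "uncovered"))
  }
  if (mu_a_cp > mu_p_ca) return(list(label = "A", rule = "uncovered"))
  if (mu_a_cp < mu_p_ca) return(list(label = "P", rule = "uncovered"))
  list(label = if (tie_rule == "prefer_P") "P" else "A", rule = "uncovered")
}

# Enumerate score pairs realizing a label pair and an ordering of the two
# classifiers' own-class confidences (conf_cp vs conf_ca in {<, =, >}).
score_pair_cases <- function(lab_cp, lab_ca, ordering) {
  conf <- switch(ordering,
    "<" = c(0.6, 0.8),
    "=" = c(0.7, 0.7),
    ">" = c(0.8, 0.6)
  )
  score_p_cp <- if (lab_cp == "P") conf[1] else 1 - conf[1]
  score_p_ca <- if (lab_ca == "P") conf[2] else 1 - conf[2]
  list(score_p_cp = score_p_cp, score_p_ca = score_p_ca)
}

# Mean CV metrics over seeds for a config; returns a named vector.
mean_cv_metrics <- function(cfg_fun, seeds, k = 5) {
  res <- sapply(seeds, function(s) {
    ds <- generate_synthetic(cfg_fun(s))
    r <- cross_validate(ds$manifest, ds$view1, ds$view2, k = k, seed = s)
    a <- r$aggregate
    g <- function(m, met) a$mean[a$model == m & a$metric == met]
    c(cp_bac = g("CP", "bac"), ca_bac = g("CA", "bac"),
      fu_bac = g("fusion", "bac"),
      cp_sen = g("CP", "sen"), ca_sen = g("CA", "sen"),
      cp_spe = g("CP", "spe"), ca_spe = g("CA", "spe"))
  })
  rowMeans(res)
}
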