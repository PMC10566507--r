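test_that("signatures are yield-blind and order-insensitive", {
  r1 <- acetamide_record(yield = 20)
  r2 <- acetamide_record(yield = 90)
  expect_identical(reaction_signature(r1), reaction_signature(r2))
  r3 <- acetamide_record()
  r3$context <- reaction_context(reagents = c("hobt", "dipea"),
                                 solvents = "dmf", temperature = 25, time = 12)
  r4 <- acetamide_record()
  r4$context <- reaction_context(reagents = c("dipea", "hobt"),
                                 solvents = "dmf", temperature = 25, time = 12)
  expect_identical(reaction_signature(r3), reaction_signature(r4))
  r5 <- acetamide_record()
  r5$context$solvents <- "thf"
  expect_false(reaction_signature(r5) == reaction_signature(r1))
})

test_that("uncertain detection groups by signature and spread", {
  base <- acetamide_record()
  recs <- lapply(seq_along(c(32, 55, 91.4)), function(i) {
    r <- acetamide_record(yield = c(32, 55, 91.4)[i])
    r$reaction_id <- paste0("u", i)
    r
  })
  other <- acetamide_record(yield = 70)
  other$reaction_id <- "solo"
  other$context$solvents <- "thf"
  ds <- reaction_dataset(c(recs, list(other)))
  groups <- find_uncertain(ds)
  expect_length(groups, 1)
  expect_setequal(groups[[1]]$reaction_ids, c("u1", "u2", "u3"))
  expect_equal(groups[[1]]$spread, 91.4 - 32)
  # identical duplicate yields are not "different yield records"
  dup <- lapply(1:2, function(i) {
    r <- acetamide_record(yield = 50); r$reaction_id <- paste0("d", i); r
  })
  expect_length(find_uncertain(reaction_dataset(dup)), 0)
  # all-unique signatures -> nothing
  expect_length(find_uncertain(subset_dataset(ds, 4)), 0)
})

test_that("cosine similarity matches a direct evaluation", {
  m <- matrix(c(1, 0, 1, 1, 0,
                1, 0, 1, 0, 0,
                0, 1, 0, 0, 1,
                1, 1, 1, 1, 1,
                0.5, 2, 0, 1, 3), 5, 5, byrow = TRUE)
  blk <- feature_block("x", m)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      direct <- sum(m[i, ] * m[j, ]) / sqrt(sum(m[i, ]^2) * sum(m[j, ]^2))
      expect_equal(pairwise_similarity(blk, i, j), direct, tolerance = 1e-12)
      expect_equal(pairwise_similarity(blk, j, i),
                   pairwise_similarity(blk, i, j))
    }
  }
  expect_equal(pairwise_similarity(blk, 2, 2), 1.0)
  zero <- feature_block("z", rbind(m, 0))
  expect_error(pairwise_similarity(zero, 1, 6), "zero vector")
})

test_that("cliff detection equals the brute-force scan and finds plants", {
  gen <- small_synthetic()
  ds <- gen$dataset
  feats <- cliff_features(ds)
  found <- find_cliffs(ds, feats)
  # brute force oracle
  ys <- yields(ds)
  ids <- vapply(ds$records, function(r) r$reaction_id, character(1))
  sigs <- vapply(ds$records, reaction_signature, character(1))
  brute <- list()
  for (i in 1:(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      if (sigs[i] == sigs[j]) next
      if (abs(ys[i] - ys[j]) < 30) next
      if (pairwise_similarity(feats, i, j) <= 0.9) next
      brute[[length(brute) + 1]] <- c(ids[i], ids[j])
    }
  }
  brute_keys <- vapply(brute, paste, character(1), collapse = "|")
  found_keys <- paste(found$id_a, found$id_b, sep = "|")
  expect_setequal(found_keys, brute_keys)
  # planted cliffs are all recovered (they were similarity-verified)
  planted_keys <- paste(gen$truth$cliff_pairs$id_a,
                        gen$truth$cliff_pairs$id_b, sep = "|")
  norm_key <- function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)
    vapply(parts, function(p) paste(sort(p), collapse = "|"), character(1))
  }
  expect_true(all(norm_key(planted_keys) %in% norm_key(found_keys)))
  # planted uncertain groups are all recovered
  det <- find_uncertain(ds)
  det_ids <- lapply(det, `[[`, "reaction_ids")
  for (grp in gen$truth$uncertain_groups) {
    expect_true(any(vapply(det_ids, function(d) setequal(d, grp), logical(1))))
  }
})

test_that("detection is monotone in both thresholds", {
  gen <- small_synthetic()
  ds <- gen$dataset
  feats <- cliff_features(ds)
  base <- find_cliffs(ds, feats, 0.9, 30)
  tighter_sim <- find_cliffs(ds, feats, 0.95, 30)
  tighter_gap <- find_cliffs(ds, feats, 0.9, 40)
  key <- function(df) paste(df$id_a, df$id_b)
  expect_true(all(key(tighter_sim) %in% key(base)))
  expect_true(all(key(tighter_gap) %in% key(base)))
  # cliff pairs and uncertain groups are disjoint by the signature rule
  unc_ids <- unlist(lapply(find_uncertain(ds), `[[`, "reaction_ids"))
  sig_of <- function(id) {
    reaction_signature(ds$records[[match(id, vapply(ds$records, function(r)
      r$reaction_id, character(1)))]])
  }
  for (k in seq_len(min(nrow(base), 20))) {
    expect_false(sig_of(base$id_a[k]) == sig_of(base$id_b[k]))
  }
})

test_that("removal bookkeeping and re-evaluation are exact", {
  gen <- small_synthetic()
  ds <- gen$dataset
  feature_fun <- function(d) {
    list(fp = assemble_reaction_features(d, c("fingerprint", "context"),
                                         roles = c("acid", "amine"),
                                         vocab = ds$context_vocab))
  }
  stack <- stack_spec(list(fp = model_spec("ridge")))
  plan <- split_plan(n_splits = 2, seed = 6)
  report <- remove_and_reevaluate(ds, feature_fun, stack, plan)
  expect_equal(report$n_after,
               report$n_before - length(report$removal_ids))
  expect_true(all(report$removal_ids %in%
                    vapply(ds$records, function(r) r$reaction_id, character(1))))
  # empty detection leaves the benchmark unchanged
  clean2 <- subset_dataset(ds, which(gen$truth$planted == "base"))
  rep2 <- remove_and_reevaluate(clean2, feature_fun, stack, plan,
                                sim_threshold = 0.999999, yield_gap = 100)
  expect_length(rep2$removal_ids, 0)
  expect_equal(rep2$before, rep2$after)
})
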