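test_that("saturation enumeration has 19 substitutions per position", {
  seqv <- toy_hydrolase_sequence()
  one <- enumerate_saturation(seqv, data.frame(start = 68, end = 68))
  expect_equal(nrow(one), 19)
  expect_true(all(one$wt == "H"))
  expect_false(any(one$mut == "H"))
  expect_equal(one$mut, sort(one$mut)) # deterministic order

  loop <- enumerate_saturation(seqv, data.frame(start = 67, end = 76))
  expect_equal(nrow(loop), 190)

  three <- enumerate_saturation(seqv, data.frame(start = c(67, 176, 320),
                                                 end = c(76, 181, 333)))
  expect_equal(nrow(three), 19 * (10 + 6 + 14))
})

test_that("enumeration rejects non-standard or out-of-range targets", {
  seqv <- c("A", "X", "G")
  expect_error(enumerate_saturation(seqv, data.frame(start = 2, end = 2)),
               "non-standard")
  expect_error(enumerate_saturation(seqv, data.frame(start = 3, end = 5)),
               "outside")
})

test_that("consensus verdicts follow the strict sign grid", {
  grid <- expand.grid(ddg_a = c(-1, 0, 1), ddg_b = c(-1, 0, 1))
  scored <- data.frame(position = seq_len(nrow(grid)), wt = "A", mut = "G",
                       ddg_a = grid$ddg_a, ddg_b = grid$ddg_b)
  filt <- consensus_filter(scored)
  stab <- filt$verdict == "stabilizing"
  expect_equal(stab, grid$ddg_a < 0 & grid$ddg_b > 0)
  expect_equal(sum(stab), 1) # only (-1, +1)
  # boundary: ddg_a exactly 0 never passes
  expect_equal(filt$verdict[filt$ddg_a == 0 & filt$ddg_b == 1],
               "not-stabilizing")
})

test_that("missing scores yield incomplete, excluded from the subset", {
  scored <- data.frame(position = c(5, 6), wt = c("A", "A"),
                       mut = c("G", "V"),
                       ddg_a = c(-1, NA), ddg_b = c(1, 2))
  filt <- consensus_filter(scored)
  expect_equal(filt$verdict, c("stabilizing", "incomplete"))
  expect_equal(stabilizing_subset(filt), "A5G")
})

test_that("the consensus filter is monotone in both scores", {
  set.seed(77)
  base <- data.frame(position = 1:50, wt = "A", mut = "G",
                     ddg_a = rnorm(50), ddg_b = rnorm(50))
  v0 <- consensus_filter(base)$verdict
  better <- base
  better$ddg_a <- better$ddg_a - abs(rnorm(50))
  better$ddg_b <- better$ddg_b + abs(rnorm(50))
  v1 <- consensus_filter(better)$verdict
  expect_true(all(!(v0 == "stabilizing" & v1 == "not-stabilizing")))
})

test_that("the fixture score table reproduces the 13-mutant consensus set", {
  seqv <- toy_hydrolase_sequence()
  cand <- enumerate_saturation(seqv, data.frame(start = c(67, 176, 320),
                                                end = c(76, 181, 333)))
  fix <- ddg_fixture_table(cand, consensus_thirteen(), seed = 3)
  filt <- consensus_filter(attach_scores(cand, fix))
  expect_setequal(stabilizing_subset(filt), consensus_thirteen())
})

test_that("surrogate scores are deterministic and order-independent", {
  seqv <- toy_hydrolase_sequence()
  a <- surrogate_scorer(seqv, 68, "A", seed = 9)
  b <- surrogate_scorer(seqv, 321, "I", seed = 9)
  a2 <- surrogate_scorer(seqv, 68, "A", seed = 9)
  expect_identical(a, a2)
  expect_false(identical(a, b))
  expect_error(surrogate_scorer(seqv, 68, "H", seed = 9), "synonymous")
  # scoring a table twice is reproducible regardless of row order
  cand <- enumerate_saturation(seqv, data.frame(start = 67, end = 70))
  s1 <- score_candidates(cand, seqv, seed = 5)
  shuffled <- cand[rev(seq_len(nrow(cand))), ]
  s2 <- score_candidates(shuffled, seqv, seed = 5)
  m <- match(paste(s1$position, s1$mut), paste(s2$position, s2$mut))
  expect_equal(s1$ddg_a, s2$ddg_a[m])
  expect_true(all(is.finite(s1$ddg_a)) && all(is.finite(s1$ddg_b)))
})

test_that("heat-map matrices carry 19 scored cells and a null wt cell", {
  seqv <- toy_hydrolase_sequence()
  cand <- enumerate_saturation(seqv, data.frame(start = 68, end = 68))
  scored <- consensus_filter(score_candidates(cand, seqv, seed = 2))
  hm <- heatmap_matrix(scored)
  expect_equal(dim(hm$ddg_a), c(1, 20))
  expect_equal(sum(!is.na(hm$ddg_a)), 19)
  expect_true(is.na(hm$ddg_a[1, "H"])) # wild type cell
  # stabilizing flags agree with the filter
  expect_equal(sum(hm$stabilizing), sum(scored$verdict == "stabilizing"))
})

test_that("heat maps round-trip through JSON unchanged", {
  seqv <- toy_hydrolase_sequence()
  cand <- enumerate_saturation(seqv, data.frame(start = c(68, 70),
                                                end = c(68, 70)))
  hm <- heatmap_matrix(consensus_filter(score_candidates(cand, seqv, 4)))
  path <- withr::local_tempfile(fileext = ".json")
  heatmap_to_json(hm, path)
  back <- heatmap_from_json(path)
  expect_equal(back$positions, hm$positions)
  expect_equal(back$wt, hm$wt)
  expect_equal(unname(back$ddg_a), unname(hm$ddg_a), tolerance = 1e-12)
  expect_equal(unname(back$stabilizing), unname(hm$stabilizing))
})
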