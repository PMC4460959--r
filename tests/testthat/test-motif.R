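mk_pwm <- function(probs, id = "m") {
  colnames(probs) <- c("A", "C", "G", "T")
  list(motif_id = id, probs = probs, nsites = NA_real_)
}

test_that("log-odds matrix follows the pseudo-frequency formula", {
  # PWM row equal to the background scores zero everywhere
  bg <- rep(0.25, 4)
  uni <- mk_pwm(matrix(0.25, 2, 4))
  expect_equal(log_odds_matrix(uni, bg), matrix(0, 2, 4,
               dimnames = list(NULL, c("A", "C", "G", "T"))),
               tolerance = 1e-12)
  # deterministic consensus row: one positive max, negative elsewhere
  cons <- mk_pwm(matrix(c(1, 0, 0, 0), 1, 4))
  lom <- log_odds_matrix(cons, bg)
  expect_gt(lom[1, "A"], 0)
  expect_true(all(lom[1, c("C", "G", "T")] < 0))
  expect_equal(which.max(lom[1, ]), c(A = 1L))
  # random PWM equals the direct element-wise formula
  set.seed(71)
  p <- matrix(rgamma(12, 1), 3, 4); p <- p / rowSums(p)
  bg2 <- c(0.3, 0.2, 0.2, 0.3)
  got <- log_odds_matrix(mk_pwm(p), bg2, pseudocount = 0.001)
  want <- log2(t((t(p) + bg2 * 0.001) / 1.001) / matrix(bg2, 3, 4,
                                                        byrow = TRUE))
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
  expect_error(log_odds_matrix(cons, c(0.5, 0.5, 0, 0)), "positive")
})

test_that("score p-value table equals exhaustive k-mer enumeration", {
  bg <- rep(0.25, 4)
  # single position: p of the best base's score is that base's probability
  one <- log_odds_matrix(mk_pwm(matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4)), bg)
  tab <- score_pvalue_table(one, bg)
  expect_equal(score_pvalue(tab, max(one)), 0.25, tolerance = 1e-12)
  # minimum possible score carries the whole mass
  expect_equal(score_pvalue(tab, min(one)), 1)

  # lengths 2..5: exact agreement with enumeration over all k-mers on the
  # quantized grid, for several random PWMs and a non-uniform background
  set.seed(81)
  for (L in 2:5) {
    p <- matrix(rgamma(4 * L, 1), L, 4); p <- p / rowSums(p)
    bg2 <- c(0.2, 0.3, 0.3, 0.2)
    lom <- log_odds_matrix(mk_pwm(p), bg2)
    tab <- score_pvalue_table(lom, bg2)
    kmers <- as.matrix(expand.grid(rep(list(1:4), L)))
    qsum <- apply(kmers, 1, function(k)
      sum(tab$qmat[cbind(seq_len(L), k)]))
    prob <- apply(kmers, 1, function(k) prod(bg2[k]))
    for (q in unique(qsum)) {
      expect_equal(tab$pvals[q + 1L], sum(prob[qsum >= q]),
                   tolerance = 1e-9)
    }
    # monotone non-increasing in the score
    expect_true(all(diff(tab$pvals) <= 1e-15))
    expect_equal(tab$pvals[1], 1)
  }
})

test_that("window scanning finds planted consensus and respects strands", {
  set.seed(91)
  cons <- "ACGTACGTTG"
  pwm <- enhancerlink:::consensus_pwm("planted", cons)
  chrom <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                 collapse = "")
  # plant the consensus 40 bp before the probe CpG at position 500
  substr(chrom, 460, 469) <- cons
  genome <- Biostrings::DNAStringSet(c(c1 = chrom))
  probes <- data.frame(id = "p1", chrom = "c1", pos = 500L, masked = FALSE,
                       stringsAsFactors = FALSE)
  hits <- scan_windows(probes, genome, list(planted = pwm))
  planted_off <- 459 - (500 - 100 - 1)  # 0-based offset within the window
  expect_true(any(hits$offset == planted_off & hits$strand == "+"))
  expect_true(all(hits$p_match < 1e-4))

  # all-N window yields no hits
  genome_n <- Biostrings::DNAStringSet(c(c1 = paste(rep("N", 1000),
                                                    collapse = "")))
  expect_equal(nrow(scan_windows(probes, genome_n, list(planted = pwm))), 0)

  # reverse-complemented genome gives the strand-swapped, mirrored hit set
  rc <- Biostrings::reverseComplement(genome)
  names(rc) <- "c1"
  probes_rc <- probes
  probes_rc$pos <- 1000L - 500L + 1L
  hits_rc <- scan_windows(probes_rc, rc, list(planted = pwm))
  W <- 201  # full window width
  mirrored <- data.frame(offset = W - 10 - hits_rc$offset,
                         strand = ifelse(hits_rc$strand == "+", "-", "+"),
                         score = hits_rc$score)
  expect_equal(
    mirrored[order(mirrored$offset, mirrored$strand), ],
    hits[order(hits$offset, hits$strand), c("offset", "strand", "score")],
    ignore_attr = TRUE, tolerance = 1e-9)

  # probe on a missing chromosome is skipped with a warning
  bad <- data.frame(id = "px", chrom = "cZ", pos = 100L, masked = FALSE)
  expect_warning(h0 <- scan_windows(bad, genome, list(planted = pwm)),
                 "absent")
  expect_equal(nrow(h0), 0)
})

test_that("motif enrichment evaluates the odds-ratio formulas", {
  # a=20, b=80, c=100, d=900: p=0.2, P=0.1, OR = 2.25
  mk_hits <- function(sel_hit, bg_hit, sel_n, bg_n) {
    sel <- sprintf("s%03d", seq_len(sel_n))
    bg_only <- sprintf("b%03d", seq_len(bg_n - sel_n))
    hits <- data.frame(
      probe_id = c(sel[seq_len(sel_hit)],
                   bg_only[seq_len(bg_hit - sel_hit)]),
      motif_id = "m1", offset = 0L, strand = "+", score = 10,
      p_match = 1e-6, stringsAsFactors = FALSE)
    list(sel = sel, bg = c(sel, bg_only), hits = hits)
  }
  x <- mk_hits(20, 120, 100, 1000)
  r <- motif_enrichment(x$sel, x$bg, x$hits)
  expect_equal(r$a, 20); expect_equal(r$b, 80)
  expect_equal(r$c, 120); expect_equal(r$d, 880)
  expect_equal(r$p_sel, 0.2, tolerance = 1e-12)
  # the printed-example counts: feed them directly through the formulas
  a <- 20; b <- 80; c_ <- 100; d <- 900
  p <- a / (a + b); P <- c_ / (c_ + d)
  expect_equal((p / (1 - p)) / (P / (1 - P)), 2.25, tolerance = 1e-12)
  expect_equal(r$sd, sqrt(1 / 20 + 1 / 80 + 1 / 120 + 1 / 880),
               tolerance = 1e-12)
  expect_equal(r$lower_ci, exp(log(r$odds_ratio) - 1.96 * r$sd),
               tolerance = 1e-12)
  # z = 1 reproduces the one-SD bound
  r1 <- motif_enrichment(x$sel, x$bg, x$hits, z = 1)
  expect_equal(r1$lower_ci, exp(log(r1$odds_ratio) - r1$sd),
               tolerance = 1e-12)

  # paired set identical to the background: OR = 1, not enriched
  same <- mk_hits(50, 50, 200, 200)
  rs <- motif_enrichment(same$sel, same$sel, same$hits)
  expect_equal(rs$odds_ratio, 1, tolerance = 1e-12)
  expect_false(rs$enriched)

  # occurrence floor: a = 9 excluded no matter the OR
  few <- mk_hits(9, 10, 100, 1000)
  rf <- motif_enrichment(few$sel, few$bg, few$hits)
  expect_gt(rf$odds_ratio, 9)
  expect_false(rf$enriched)

  # zero cell: unevaluable
  z0 <- mk_hits(100, 100, 100, 1000)  # b = 0
  expect_false(motif_enrichment(z0$sel, z0$bg, z0$hits)$evaluable)

  # doubling all counts keeps OR, shrinks SD
  dbl <- mk_hits(40, 240, 200, 2000)
  rd <- motif_enrichment(dbl$sel, dbl$bg, dbl$hits)
  expect_equal(rd$odds_ratio, r$odds_ratio, tolerance = 1e-12)
  expect_lt(rd$sd, r$sd)

  expect_error(motif_enrichment(c("zzz"), x$bg, x$hits), "subset")
})
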