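test_that("target-lesion selection follows size order with per-organ caps", {
  b <- dplyr::bind_rows(
    mrow("P", 0, "La", "liver", 30), mrow("P", 0, "Lb", "liver", 20),
    mrow("P", 0, "Lc", "liver", 10), mrow("P", 0, "Ln", "node", 15)
  )
  expect_equal(select_target_lesions(b), c("La", "Lb", "Ln"))
  one <- mrow("P", 0, "L1", diameter_mm = 12)
  expect_equal(select_target_lesions(one), "L1")
  none <- mrow("P", 0, "L1", diameter_mm = 0)
  expect_error(select_target_lesions(none), "no measurable disease")
})

test_that("greedy selection maximises total diameter under the caps", {
  # brute-force oracle: enumerate subsets respecting both caps
  brute_best <- function(b, max_total = 5, max_per_organ = 2) {
    ids <- b$lesion_id
    best <- 0
    for (k in 1:min(max_total, length(ids))) {
      for (sel in utils::combn(seq_along(ids), k, simplify = FALSE)) {
        if (any(table(b$organ[sel]) > max_per_organ)) next
        best <- max(best, sum(b$diameter_mm[sel]))
      }
    }
    best
  }
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    b <- tibble::tibble(
      patient_id = "P", day = 0L,
      lesion_id = sprintf("L%02d", 1:n),
      organ = sample(c("liver", "node", "lung", "peritoneum"), n, TRUE),
      diameter_mm = round(runif(n, 5, 60), 1),
      attenuation_hu = NA_real_, is_new = FALSE,
      nontarget_progression = FALSE
    )
    sel <- select_target_lesions(b)
    got <- sum(b$diameter_mm[match(sel, b$lesion_id)])
    expect_equal(got, brute_best(b))
  }
})

test_that("assessment summaries: diameter sums and unweighted HU means", {
  a <- dplyr::bind_rows(
    mrow("P", 90, "L1", diameter_mm = 30, attenuation_hu = 120),
    mrow("P", 90, "L2", diameter_mm = 20, attenuation_hu = 80),
    mrow("P", 90, "L3", diameter_mm = 15)
  )
  expect_equal(sum_of_diameters(a, c("L1", "L2", "L3")), 65)
  expect_equal(sum_of_diameters(a, "L3"), 15)
  expect_error(sum_of_diameters(a, c("L1", "L9")), "L9")
  expect_equal(mean_attenuation(a, c("L1", "L2")), 100)
  expect_equal(mean_attenuation(a, c("L2", "L3")), 80)  # mean over available
  expect_true(is.na(mean_attenuation(a, "L3")))
  zero <- mrow("P", 90, "L1", diameter_mm = 0)
  expect_equal(sum_of_diameters(zero, "L1"), 0)
})

recist_label_for <- function(baseline, followups) {
  m <- series_patient("P", c(0, seq_along(followups) * 90),
                      c(baseline, followups))
  r <- classify_recist(m)
  as.character(r$label)
}

test_that("RECIST rules fire at the documented thresholds", {
  expect_equal(recist_label_for(100, 65), "PR")      # -35%
  expect_equal(recist_label_for(100, 70), "PR")      # exactly -30% is PR
  expect_equal(recist_label_for(100, 121), "PD")     # +21%, +21 mm vs nadir
  expect_equal(recist_label_for(100, 120), "PD")     # exactly +20%/+20 mm
  expect_equal(recist_label_for(20, 24), "SD")       # +20% but only +4 mm
  expect_equal(recist_label_for(100, 0), "CR")
  expect_equal(recist_label_for(100, 95), "SD")
  # nadir tracking: deep response then regrowth from nadir
  expect_equal(recist_label_for(100, c(40, 50)), c("PR", "PD"))  # +25% vs 40
  # new lesion forces PD even while shrinking
  m <- series_patient("P", c(0, 90), c(100, 60), new_at = 90)
  expect_equal(as.character(classify_recist(m)$label), "PD")
  expect_equal(classify_recist(m)$trigger, "new_lesion")
})

test_that("Choi rules combine size and attenuation as documented", {
  choi_label <- function(sums, hus) {
    m <- series_patient("P", c(0, seq_along(sums[-1]) * 90), sums, hus)
    as.character(classify_choi(m)$label)
  }
  expect_equal(choi_label(c(100, 95), c(100, 80)), "PR")    # HU -20%
  expect_equal(choi_label(c(100, 112), c(100, 70)), "PR")   # grown but hypoattenuating
  expect_equal(choi_label(c(100, 112), c(100, 95)), "PD")   # +12%, HU -5%
  expect_equal(choi_label(c(100, 89), c(100, 95)), "PR")    # size -11%
  expect_equal(choi_label(c(100, 90), c(100, 85)), c("PR")) # both at threshold
  expect_equal(choi_label(c(100, 95), c(100, 99)), "SD")
  expect_equal(choi_label(c(100, 0), c(100, NA)), "CR")
  # HU missing at follow-up: attenuation clause not met, flagged
  r <- classify_choi(series_patient("P", c(0, 90), c(100, 95), c(100, NA)))
  expect_equal(as.character(r$label), "SD")
  expect_equal(r$flag, "hu_unavailable")
  # missing baseline HU: warning + size-only classification
  expect_warning(
    r2 <- classify_choi(series_patient("P", c(0, 90), c(100, 85),
                                       c(NA, 80))),
    "baseline HU")
  expect_equal(as.character(r2$label), "PR")
  expect_equal(r2$flag, "no_baseline_hu")
})

test_that("classification matches a brute-force rule oracle on a threshold grid", {
  pcts <- c(-40, -30.5, -30, -29.5, -15, -10.5, -10, -9.5, 0,
            9.5, 10, 10.5, 19.5, 20, 20.5, 35)
  base_sums <- c(20, 100)   # small sums probe the 5-mm absolute rule
  hu_pcts <- c(NA, -25, -15.5, -15, -14.5, 0, 10)
  for (b in base_sums) {
    for (p in pcts) {
      s1 <- b * (1 + p / 100)
      for (hp in hu_pcts) {
        hu1 <- if (is.na(hp)) NA_real_ else 100 * (1 + hp / 100)
        m <- series_patient("P", c(0, 90), c(b, s1), c(100, hu1))
        got_r <- as.character(classify_recist(m)$label)
        got_c <- as.character(classify_choi(m)$label)
        # first follow-up: nadir == baseline
        expect_equal(got_r, oracle_recist(p, p, s1 - b, s1), info = paste(b, p, hp))
        expect_equal(got_c, oracle_choi(p, hp, s1), info = paste(b, p, hp))
      }
    }
  }
})

test_that("a RECIST PR is always a Choi PR (implication property)", {
  set.seed(5)
  n_pat <- 400
  m <- dplyr::bind_rows(lapply(seq_len(n_pat), function(i) {
    base <- runif(1, 20, 150)
    sums <- pmax(0, base * cumprod(c(1, runif(3, 0.4, 1.6))))
    hus <- pmax(40, 110 * cumprod(c(1, runif(3, 0.7, 1.2))))
    series_patient(sprintf("P%04d", i), c(0, 90, 180, 270), sums, hus)
  }))
  rec <- classify_recist(m)
  cho <- classify_choi(m)
  joined <- dplyr::inner_join(
    dplyr::select(rec, "patient_id", "day", recist = "label"),
    dplyr::select(cho, "patient_id", "day", choi = "label"),
    by = c("patient_id", "day")
  )
  pr <- joined[joined$recist == "PR", ]
  expect_gt(nrow(pr), 0)
  expect_true(all(pr$choi == "PR"))
})

test_that("series terminate at first PD and severity is monotone", {
  m <- series_patient("P", c(0, 90, 180, 270), c(100, 130, 90, 80))
  r <- classify_recist(m)
  expect_equal(nrow(r), 1)            # stops at day-90 PD
  expect_equal(as.character(r$label), "PD")
  ch <- classify_choi(series_patient("P", c(0, 90, 180), c(100, 115, 90),
                                     c(100, 100, 100)))
  expect_equal(nrow(ch), 1)
  # monotone severity: inflating a follow-up sum never rescues a PD
  set.seed(9)
  for (i in 1:50) {
    b <- runif(1, 30, 120)
    s <- runif(1, 0.5, 2) * b
    lab1 <- recist_label_for(b, s)
    lab2 <- recist_label_for(b, s * runif(1, 1, 1.5))
    if (lab1 == "PD") expect_equal(lab2, "PD")
  }
})

test_that("landmark lookup carries progression forward and respects the window", {
  m <- series_patient("P", c(0, 100, 350), c(100, 130, 140))
  r <- classify_recist(m)
  expect_equal(as.character(response_at(r, 183, 60)$label), "PD")

  m2 <- series_patient("Q", c(0, 170, 350), c(100, 95, 94))
  r2 <- classify_recist(m2)
  at <- response_at(r2, 183, 60)
  expect_equal(at$day, 170L)
  expect_equal(as.character(at$label), "SD")

  m3 <- series_patient("R", c(0, 400), c(100, 95))
  expect_true(is.na(response_at(classify_recist(m3), 183, 60)$label))
})

test_that("transition tables cross-tabulate landmark labels with folded CR", {
  m <- dplyr::bind_rows(
    series_patient("A", c(0, 180), c(100, 60), c(100, 70)),   # PR / PR
    series_patient("B", c(0, 180), c(100, 98), c(100, 99)),   # SD / SD
    series_patient("C", c(0, 180), c(100, 130), c(100, 101))  # PD / PD
  )
  tt <- transition_table(classify_recist(m), classify_choi(m))
  expect_equal(tt$n, 3)
  expect_equal(diag(tt$counts), c(PR = 1L, SD = 1L, PD = 1L))
  expect_equal(sum(tt$counts), 3)
  # margins equal per-criterion label counts
  expect_equal(unname(rowSums(tt$counts)), c(1L, 1L, 1L))
  # empty cohort
  empty <- classify_recist(
    lesion_cohort(mrow("Z", 0, "L1")[0, ],
                  tibble::tibble(patient_id = character(),
                                 death_day = integer(),
                                 last_followup_day = integer())))
  t0 <- transition_table(empty, empty)
  expect_equal(t0$n, 0)
  expect_true(all(t0$counts == 0))
})

test_that("Cohen's kappa matches hand formula, oracle and invariances", {
  tab <- matrix(c(10, 0, 0, 26, 11, 7, 1, 1, 22), 3, byrow = TRUE)
  k <- cohens_kappa(tab)
  expect_equal(round(k, 3), 0.392)
  expect_equal(k, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  expect_equal(cohens_kappa(diag(c(5, 3, 2))), 1)
  # invariant under simultaneous row+column permutation
  p <- c(3, 1, 2)
  expect_equal(cohens_kappa(tab[p, p]), k, tolerance = 1e-12)
  expect_error(cohens_kappa(matrix(0, 3, 3)), "empty")
  # kappa near zero under independent margins
  set.seed(1)
  r <- sample(1:3, 2e4, TRUE, prob = c(0.2, 0.5, 0.3))
  c_ <- sample(1:3, 2e4, TRUE, prob = c(0.4, 0.3, 0.3))
  expect_lt(abs(cohens_kappa(table(r, c_))), 0.02)
})

test_that("published-style marginals uniquely reconstruct the 3x3 table", {
  tt <- reconstruct_transition_table(
    recist_margins_pct = c(12.8, 56.4, 30.7),
    choi_margins_pct = c(47.4, 15.3, 37.1),
    n = 78, sd_to_pr = 26, sd_to_pd = 7
  )
  expect_equal(unname(tt$counts),
               matrix(c(10, 0, 0, 26, 11, 7, 1, 1, 22), 3, byrow = TRUE))
  expect_equal(tt$n, 78)
  expect_error(
    reconstruct_transition_table(c(50, 30, 20), c(10, 10, 80), 10, 9, 9),
    "inconsistent|sum")
})
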