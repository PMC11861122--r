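# treatment patterns: yearly counts, state sweep, switches, lines, Sankey

cfg <- itp_config()
fx <- fixture_small()
sel <- select_cohort(fx, cfg)
co <- sel$cohort
eps <- build_episodes(fx$prescriptions[patient_id %in% co$patient_id], cfg)

test_that("yearly modality counts count each patient once per year", {
  yc <- yearly_modality_counts(fx, co, cfg)
  # F15: four ROMI scripts in 2019 -> one patient
  expect_equal(yc[yc$year == 2019 & yc$modality == "ROMI", n], 1L)
  # 2019 CS users: F12, F18
  expect_equal(yc[yc$year == 2019 & yc$modality == "CS", n], 2L)
  # a CS+EPAG patient counts once under each modality
  expect_equal(yc[yc$year == 2019 & yc$modality == "EPAG", n], 2L)
  expect_equal(yc[yc$year == 2019 & yc$modality == "any", n], 3L)
  # percentages relative to any-treatment denominator
  expect_equal(yc[yc$year == 2019 & yc$modality == "CS", pct],
               round(100 * 2 / 3, 2))
})

test_that("state sweep matches the hand-derived add-on/switch states", {
  st <- derive_states(eps, fx$procedures, cfg)
  f12 <- st[st$patient_id == "F12"]
  expect_equal(f12$label, c("CS", "CS|EPAG", "EPAG"))
  expect_equal(f12$start,
               as.Date(c("2019-02-01", "2019-03-15", "2019-04-02")))
  f13 <- st[st$patient_id == "F13"]
  expect_equal(f13$label, c("CS", "EPAG", "CS"))  # re-administration visible
  f14 <- st[st$patient_id == "F14"]
  expect_equal(f14$label, c("CS", "Splenectomy"))
  # single CS episode -> single state
  expect_equal(st[st$patient_id == "F01", label], "CS")
  # consecutive states always differ
  dups <- st[, .(bad = any(label == data.table::shift(label, fill = ""))),
             by = patient_id]
  expect_false(any(dups$bad))
})

test_that("state derivation equals the brute-force per-day scan", {
  set.seed(7)
  for (rep in 1:40) {
    n_iv <- sample.int(6L, 1L)
    iv <- data.frame(
      label = sample(c("CS", "EPAG", "ROMI", "RTX"), n_iv, replace = TRUE),
      start = sample.int(200L, n_iv, replace = TRUE))
    iv$end <- iv$start + sample.int(90L, n_iv, replace = TRUE)
    eps_t <- data.table::data.table(
      patient_id = "X", drug_class = iv$label, episode = seq_len(n_iv),
      start = as.Date(iv$start, origin = "2019-12-31"),
      end = as.Date(iv$end, origin = "2019-12-31"),
      end_exclusive = as.Date(iv$end + 1L, origin = "2019-12-31"),
      n_rx = 1L)
    st <- derive_states(eps_t, fx$procedures[0L], cfg)
    orc <- oracle_states(iv)
    expect_equal(st$label, orc$label)
    expect_equal(as.integer(st$start - as.Date("2019-12-31")), orc$start)
    expect_equal(as.integer(st$end - as.Date("2019-12-31")), orc$end)
  }
})

test_that("switch sequences collapse duplicates and pool rare patterns", {
  st <- derive_states(eps, fx$procedures, cfg)
  sw <- switch_sequence(st, itp_config(min_pattern_n = 1L))
  f12 <- sw$sequences[sw$sequences$patient_id == "F12"]
  expect_equal(f12$label, c("CS", "CS|EPAG", "EPAG"))
  expect_equal(max(f12$switch_index), 2L)
  # no two equal consecutive labels anywhere
  bad <- sw$sequences[, .(bad = any(label == data.table::shift(label,
                                                              fill = ""))),
                      by = patient_id]
  expect_false(any(bad$bad))
  # with min_pattern_n = 5 every fixture pattern except bare CS is rare
  sw5 <- switch_sequence(st, cfg)
  lab1 <- sw5$sequences[sw5$sequences$switch_index == 1L, label]
  expect_true(all(lab1 == "Others2"))
})

test_that("line derivation follows the combo window rule", {
  ln <- derive_lines(eps, fx$procedures, cfg)
  lines <- ln$lines
  # EPAG added 42 days after CS start -> second line
  f12 <- lines[lines$patient_id == "F12"]
  expect_equal(f12$regimen, c("CS", "EPAG"))
  # EPAG within 7 days of CS -> first-line combination "CS|EPAG"
  f18 <- lines[lines$patient_id == "F18"]
  expect_equal(f18$regimen, "CS|EPAG")
  # single treatment -> one line
  expect_equal(lines[lines$patient_id == "F01", regimen], "CS")
  # splenectomy appears as its own line
  f14 <- lines[lines$patient_id == "F14"]
  expect_equal(f14$regimen, c("CS", "Splenectomy"))
  # every treated patient has exactly one line-1 regimen
  expect_equal(anyDuplicated(lines[lines$line_index == 1L, patient_id]), 0L)
  # percentages sum to 100 per line
  sums <- tapply(ln$table$pct, ln$table$line_index, sum)
  expect_true(all(abs(sums - 100) < 0.1))
})

test_that("sankey export conserves counts and round-trips", {
  st <- derive_states(eps, fx$procedures, cfg)
  sw <- switch_sequence(st, itp_config(min_pattern_n = 1L))
  js <- sankey_export(sw$flows)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(sum(parsed$links$value), sum(sw$flows$n))
  # outflow of any node <= inflow (with termination); initial nodes exempt
  for (nid in parsed$nodes$id[parsed$nodes$switch_index > 0L]) {
    inflow <- sum(parsed$links$value[parsed$links$target == nid])
    outflow <- sum(parsed$links$value[parsed$links$source == nid])
    expect_lte(outflow, inflow)
  }
  # single patient CS -> EPAG: 2 nodes, 1 link of value 1
  one <- data.table::data.table(patient_id = "Z", state_index = 1:2,
                                start = as.Date("2020-01-01") + c(0, 50),
                                end = as.Date("2020-01-01") + c(49, 99),
                                label = c("CS", "EPAG"))
  sw1 <- switch_sequence(one, itp_config(min_pattern_n = 1L))
  p1 <- jsonlite::fromJSON(sankey_export(sw1$flows))
  expect_equal(nrow(p1$nodes), 2L)
  expect_equal(p1$links$value, 1L)
})
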