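# Treatment patterns: yearly modality counts, active-set treatment states,
# switch sequences with Sankey export, and treatment-line derivation.

CLASS_ORDER <- c("CS", "EPAG", "ROMI", "RTX", "Splenectomy", "Others")

class_label <- function(drug_class) {
  ifelse(drug_class == "OTHER_IS", "Others", drug_class)
}

canon_label <- function(classes) {
  paste(CLASS_ORDER[sort(match(unique(classes), CLASS_ORDER))], collapse = "|")
}

#' Patients per treatment modality per calendar year
#'
#' A patient counts once per modality per year regardless of how many
#' prescriptions (or procedures) they had; only events inside the patient's
#' assessment period count. The percentage denominator is the number of
#' patients with any ITP treatment in that year.
#'
#' @param claims a `claims` object.
#' @param cohort the cohort table from [select_cohort()].
#' @param config an [itp_config()] object.
#' @return data.table: `year`, `modality`, `n`, `denom`, `pct` (modalities:
#'   drug classes, `TPO_RA` = EPAG or ROMI, `splenectomy`, `any`).
#' @export
yearly_modality_counts <- function(claims, cohort, config = itp_config()) {
  win <- cohort[, .(patient_id, entry_date, assessment_end)]
  rx <- claims$prescriptions[win, on = "patient_id", nomatch = NULL]
  rx <- rx[date >= entry_date & date <= assessment_end,
           .(patient_id, date, modality = drug_class)]
  pr <- claims$procedures[procedure == "splenectomy"][
    win, on = "patient_id", nomatch = NULL]
  pr <- pr[date >= entry_date & date <= assessment_end,
           .(patient_id, date, modality = "splenectomy")]
  ev <- rbind(rx, pr)
  ev[, year := year_of(date)]
  ev <- ev[year %in% config$yearly_count_years]
  tpo <- ev[modality %in% c("EPAG", "ROMI")][, modality := "TPO_RA"]
  anyt <- data.table::copy(ev)[, modality := "any"]
  ev <- unique(rbind(ev, tpo, anyt)[, .(patient_id, year, modality)])
  tab <- ev[, .(n = data.table::uniqueN(patient_id)), by = .(year, modality)]
  denom <- tab[modality == "any", .(year, denom = n)]
  tab <- denom[tab, on = "year"]
  tab[, pct := round(100 * n / denom, 2)]
  data.table::setorder(tab, year, modality)
  tab[]
}

#' Derive treatment states by an active-set sweep over episode boundaries
#'
#' Each maximal interval over which the set of active treatments is constant
#' is one state; intervals with no active treatment close the current state
#' but do not emit one. Splenectomy enters the active set from its date for
#' `splenectomy_state_days` (default 90). Consecutive states with identical
#' active sets (possible across untreated gaps) are merged so that
#' consecutive states always differ.
#'
#' @param episodes output of [build_episodes()] for all drug classes.
#' @param procedures the procedures table.
#' @param config an [itp_config()] object.
#' @return data.table: `patient_id`, `state_index`, `start`, `end`, `label`
#'   (active classes joined by "|" in canonical order CS, EPAG, ROMI, RTX,
#'   Splenectomy, Others).
#' @export
derive_states <- function(episodes, procedures, config = itp_config()) {
  iv <- episodes[, .(patient_id, label = class_label(drug_class),
                     start = as.integer(start), end = as.integer(end))]
  spl <- procedures[procedure == "splenectomy",
                    .(patient_id, label = "Splenectomy",
                      start = as.integer(date),
                      end = as.integer(date) + config$splenectomy_state_days - 1L)]
  iv <- rbind(iv, spl)
  if (nrow(iv) == 0L) {
    return(data.table::data.table(patient_id = character(0),
                                  state_index = integer(0),
                                  start = as.Date(character(0)),
                                  end = as.Date(character(0)),
                                  label = character(0)))
  }
  bounds <- unique(rbind(iv[, .(patient_id, b = start)],
                         iv[, .(patient_id, b = end + 1L)]))
  data.table::setorder(bounds, patient_id, b)
  seg <- bounds[, .(s = b[-.N], e = b[-1L] - 1L), by = patient_id]
  seg <- seg[e >= s]
  hits <- iv[seg, on = .(patient_id, start <= s, end >= s),
             .(patient_id, s = x.start, seg_s = i.s, seg_e = i.e,
               label = x.label), nomatch = NULL]
  lab <- hits[, .(label = canon_label(label)), by = .(patient_id, seg_s, seg_e)]
  data.table::setorder(lab, patient_id, seg_s)
  # merge consecutive identical labels (also across untreated gaps)
  lab[, new_state := label != data.table::shift(label, fill = ""),
      by = patient_id]
  lab[, state_index := cumsum(new_state), by = patient_id]
  st <- lab[, .(start = as.Date(min(seg_s), origin = "1970-01-01"),
                end = as.Date(max(seg_e), origin = "1970-01-01"),
                label = label[1L]),
            by = .(patient_id, state_index)]
  st[]
}

#' Per-patient switch sequences and population flow table
#'
#' Collapses each patient's state labels (consecutive duplicates already
#' merged) to an ordered sequence truncated after `max_switches` switches.
#' Full patterns occurring fewer than `min_pattern_n` times have every label
#' after the initial state relabelled "Others2"; flows are then counted per
#' switch index.
#'
#' @param states output of [derive_states()].
#' @param config an [itp_config()] object.
#' @return list: `sequences` (`patient_id`, `switch_index` starting at 0,
#'   `label`), `flows` (`switch_index` of the destination, `from`, `to`, `n`),
#'   `patterns` (pattern string and count, before rare-pattern relabelling).
#' @export
switch_sequence <- function(states, config = itp_config()) {
  seqs <- states[, .(label = label,
                     switch_index = seq_len(.N) - 1L), by = patient_id]
  seqs <- seqs[switch_index <= config$max_switches]
  pat <- seqs[, .(pattern = paste(label, collapse = " -> ")), by = patient_id]
  pat_n <- pat[, .(n = .N), by = pattern]
  rare <- pat_n[n < config$min_pattern_n, pattern]
  seqs <- pat[seqs, on = "patient_id"]
  seqs[pattern %in% rare & switch_index > 0L, label := "Others2"]
  # relabelling can create consecutive duplicates; keep indices as-is but
  # drop repeated Others2 steps beyond the first
  seqs[, dup := label == data.table::shift(label, fill = "") &
         label == "Others2", by = patient_id]
  seqs <- seqs[dup == FALSE][, dup := NULL]
  seqs[, switch_index := seq_len(.N) - 1L, by = patient_id]
  flows <- seqs[, .(from = label[-.N], to = label[-1L],
                    switch_index = seq_len(.N - 1L)),
                by = patient_id][
                  , .(n = .N), by = .(switch_index, from, to)]
  data.table::setorder(flows, switch_index, from, to)
  list(sequences = seqs[, .(patient_id, switch_index, label)],
       flows = flows[], patterns = pat_n[order(-n)])
}

#' Derive treatment lines from episode starts
#'
#' Line 1 comprises every treatment class starting within `combo_window_days`
#' (default 14) of the first treatment start; a subsequent line begins when a
#' class not in the current line's regimen starts more than the window after
#' the line start, and absorbs all classes starting within the window of the
#' new line start. Regimen labels join classes with "|" in canonical order.
#'
#' @param episodes output of [build_episodes()].
#' @param procedures the procedures table.
#' @param config an [itp_config()] object.
#' @return list: `lines` (`patient_id`, `line_index`, `regimen`, `start`) and
#'   `table` (line x regimen, `n`, `pct`; percentages sum to 100 per line).
#' @export
derive_lines <- function(episodes, procedures, config = itp_config()) {
  starts <- episodes[, .(patient_id, label = class_label(drug_class),
                         start = as.integer(start))]
  spl <- procedures[procedure == "splenectomy",
                    .(patient_id, label = "Splenectomy",
                      start = as.integer(date))]
  starts <- rbind(starts, spl)
  data.table::setorder(starts, patient_id, start, label)
  w <- config$combo_window_days
  lines <- starts[, {
    li <- integer(0); reg <- character(0); st <- integer(0)
    cur <- 0L
    cur_reg <- character(0)
    cur_start <- -Inf
    for (i in seq_len(.N)) {
      if (cur == 0L ||
          (!(label[i] %in% cur_reg) && start[i] > cur_start + w)) {
        cur <- cur + 1L
        cur_start <- start[i]
        cur_reg <- unique(label[start >= cur_start & start <= cur_start + w])
        li <- c(li, cur); st <- c(st, cur_start)
        reg <- c(reg, canon_label(cur_reg))
      }
    }
    list(line_index = li, regimen = reg,
         start = as.Date(st, origin = "1970-01-01"))
  }, by = patient_id]
  tab <- lines[, .(n = .N), by = .(line_index, regimen)]
  tab[, denom := sum(n), by = line_index]
  tab[, pct := round(100 * n / denom, 2)]
  data.table::setorder(tab, line_index, -n, regimen)
  list(lines = lines[], table = tab[])
}

#' Export a switch-flow table as Sankey nodes/links JSON
#'
#' Nodes are keyed by (switch index, label); link values are patient counts.
#' Total outflow of a node never exceeds its inflow (patterns may terminate).
#'
#' @param flows the `flows` table from [switch_sequence()].
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when `path` is given.
#' @export
sankey_export <- function(flows, path = NULL) {
  nodes <- unique(rbind(
    flows[, .(switch_index = switch_index - 1L, label = from)],
    flows[, .(switch_index = switch_index, label = to)]))
  data.table::setorder(nodes, switch_index, label)
  nodes[, id := .I - 1L]
  links <- nodes[, .(switch_index = switch_index + 1L, from = label,
                     source = id)][flows, on = .(switch_index, from)]
  links <- nodes[, .(switch_index, to = label, target = id)][
    links, on = .(switch_index, to)]
  out <- list(
    nodes = nodes[, .(id, switch_index, label)],
    links = links[, .(source, target, value = n)])
  js <- jsonlite::toJSON(out, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
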