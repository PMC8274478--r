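#' Read note events from a partwise musicXML score
#'
#' Extracts spelled pitches with onset bar, within-bar position and duration
#' from a `score-partwise` document. Handles `<chord/>`, `<backup>`,
#' `<forward>`, rests, per-measure `divisions` and time-signature changes.
#' Unpitched or unspelled content is skipped; ties are read as separate
#' sounding events (adequate for pitch-class clouds).
#'
#' @param path musicXML file path.
#' @return a [note_events()] data frame.
#' @export
read_musicxml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "score-partwise") {
    stop("expected a score-partwise musicXML document")
  }
  rows <- list()
  fill_forward <- function(v, default) {
    if (all(is.na(v))) return(rep(default, length(v)))
    i <- cummax(ifelse(is.na(v), 0L, seq_along(v)))
    out <- ifelse(i == 0L, default, v[pmax(i, 1L)])
    out
  }
  for (part in xml2::xml_find_all(doc, "./part")) {
    part_id <- xml2::xml_attr(part, "id")
    meas_set <- xml2::xml_find_all(part, "./measure")
    # attributes persist until changed: pull them vectorised, fill forward
    div_v <- fill_forward(
      xml2::xml_double(xml2::xml_find_first(meas_set,
                                            "./attributes/divisions")), 1)
    beats_v <- fill_forward(
      xml2::xml_double(xml2::xml_find_first(meas_set,
                                            "./attributes/time/beats")), 4)
    bt_v <- fill_forward(
      xml2::xml_double(xml2::xml_find_first(meas_set,
                                            "./attributes/time/beat-type")), 4)
    has_bf <- !is.na(xml2::xml_find_first(part, ".//backup | .//forward"))
    bar_i <- 0L
    for (meas in meas_set) {
      bar_i <- bar_i + 1L
      bar_div <- div_v[bar_i] * beats_v[bar_i] * 4 / bt_v[bar_i]
      cursor <- 0
      prev_onset <- 0
      # fast path: no backup/forward, so note order is cursor order and all
      # fields can be pulled with vectorised xpath over the note nodeset
      if (!has_bf) {
        ns <- xml2::xml_find_all(meas, "./note")
        if (length(ns) == 0L) next
        dur <- xml2::xml_double(xml2::xml_find_first(ns, "./duration"))
        dur[is.na(dur)] <- 0
        is_chord <- !is.na(xml2::xml_find_first(ns, "./chord"))
        adv <- ifelse(is_chord, 0, dur)
        onset <- cumsum(c(0, adv[-length(adv)]))
        # a chord note sounds at its principal (previous non-chord) onset
        for (ii in which(is_chord)) onset[ii] <- onset[ii - 1L]
        step <- xml2::xml_text(xml2::xml_find_first(ns, "./pitch/step"))
        alter <- xml2::xml_double(xml2::xml_find_first(ns, "./pitch/alter"))
        alter[is.na(alter)] <- 0
        octv <- xml2::xml_double(xml2::xml_find_first(ns, "./pitch/octave"))
        pitched <- !is.na(step)
        if (any(pitched)) {
          rows[[length(rows) + 1L]] <- data.frame(
            part = part_id, bar = bar_i, beat = onset[pitched] / bar_div,
            duration = dur[pitched] / bar_div, step = step[pitched],
            alter = as.integer(alter[pitched]),
            octave = as.integer(octv[pitched]), stringsAsFactors = FALSE)
        }
        next
      }
      for (el in xml2::xml_children(meas)) {
        nm <- xml2::xml_name(el)
        if (nm == "backup") {
          cursor <- cursor -
            as.numeric(xml2::xml_text(xml2::xml_find_first(el, "./duration")))
        } else if (nm == "forward") {
          cursor <- cursor +
            as.numeric(xml2::xml_text(xml2::xml_find_first(el, "./duration")))
        } else if (nm == "note") {
          dur_node <- xml2::xml_find_first(el, "./duration")
          dur <- if (is.na(dur_node)) 0
                 else as.numeric(xml2::xml_text(dur_node))
          is_chord <- !is.na(xml2::xml_find_first(el, "./chord"))
          onset <- if (is_chord) prev_onset else cursor
          pitch <- xml2::xml_find_first(el, "./pitch")
          if (!is.na(pitch)) {
            step <- xml2::xml_text(xml2::xml_find_first(pitch, "./step"))
            alt_node <- xml2::xml_find_first(pitch, "./alter")
            alter <- if (is.na(alt_node)) 0L
                     else as.integer(xml2::xml_text(alt_node))
            octv <- as.integer(
              xml2::xml_text(xml2::xml_find_first(pitch, "./octave")))
            rows[[length(rows) + 1L]] <- data.frame(
              part = part_id, bar = bar_i, beat = onset / bar_div,
              duration = dur / bar_div, step = step, alter = alter,
              octave = octv, stringsAsFactors = FALSE)
          }
          if (!is_chord) {
            prev_onset <- cursor
            cursor <- cursor + dur
          }
        }
      }
    }
  }
  if (length(rows) == 0L) stop("no pitched notes found in ", path)
  d <- do.call(rbind, rows)
  note_events(d$part, d$bar, d$beat, d$duration, d$step, d$alter, d$octave)
}

#' Write note events as a partwise musicXML score
#'
#' Emits a minimal `score-partwise` document in 4/4 with fixed divisions.
#' Notes in the same part at the same onset become chords; remaining time in
#' a bar is filled with rests so cursors stay consistent.
#'
#' @param notes a [note_events()] data frame.
#' @param path output path.
#' @param divisions divisions per quarter note (default 480).
#' @export
write_musicxml <- function(notes, path, divisions = 480L) {
  bar_div <- divisions * 4L              # 4/4 throughout
  n_bars <- max(notes$bar)
  parts <- sort(unique(notes$part))
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<score-partwise version="3.1">',
           "  <part-list>")
  for (p in parts) {
    out <- c(out, sprintf('    <score-part id="%s"><part-name>%s</part-name></score-part>',
                          p, p))
  }
  out <- c(out, "  </part-list>")
  for (p in parts) {
    out <- c(out, sprintf('  <part id="%s">', p))
    np <- notes[notes$part == p, ]
    for (b in seq_len(n_bars)) {
      out <- c(out, sprintf('    <measure number="%d">', b))
      if (b == 1L) {
        out <- c(out, sprintf("      <attributes><divisions>%d</divisions><time><beats>4</beats><beat-type>4</beat-type></time></attributes>",
                              divisions))
      }
      nb <- np[np$bar == b, ]
      nb <- nb[order(nb$beat), ]
      cursor <- 0L
      i <- 1L
      while (i <= nrow(nb)) {
        onset <- as.integer(round(nb$beat[i] * bar_div))
        if (onset > cursor) {
          out <- c(out, sprintf("      <note><rest/><duration>%d</duration></note>",
                                onset - cursor))
          cursor <- onset
        }
        same <- which(abs(nb$beat - nb$beat[i]) < 1e-9)
        same <- same[same >= i]
        dur <- as.integer(round(nb$duration[i] * bar_div))
        for (j in seq_along(same)) {
          r <- nb[same[j], ]
          chord_tag <- if (j > 1L) "<chord/>" else ""
          alter_tag <- if (r$alter != 0L) {
            sprintf("<alter>%d</alter>", r$alter)
          } else ""
          out <- c(out, sprintf(
            "      <note>%s<pitch><step>%s</step>%s<octave>%d</octave></pitch><duration>%d</duration></note>",
            chord_tag, r$step, alter_tag, r$octave, dur))
        }
        cursor <- cursor + dur
        i <- max(same) + 1L
      }
      if (cursor < bar_div) {
        out <- c(out, sprintf("      <note><rest/><duration>%d</duration></note>",
                              bar_div - cursor))
      }
      out <- c(out, "    </measure>")
    }
    out <- c(out, "  </part>")
  }
  out <- c(out, "</score-partwise>")
  writeLines(out, path)
  invisible(path)
}
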