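# Clinical sequence grammar: which DMT sequences are plausible.

#' Construct a treatment sequence
#'
#' A sequence is a main chain of treatment lines 1a, 2, 3, 4 (two to four
#' drugs) plus an optional line-1b drug. Line 1b is a branch, not a chain
#' link: it is entered only when the patient leaves line 1a for adverse
#' events, and is followed by line 2 either way.
#'
#' @param lines Character vector of DMT names for the main chain, in order
#'   (line 1a, then lines 2, 3, 4 as present).
#' @param line1b Optional DMT name for the adverse-event branch of line 1.
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(lines, line1b = NULL) {
  lines <- as.character(lines)
  nlab <- length(lines) + as.integer(!is.null(line1b))
  if (nlab < 2 || nlab > 5)
    stop("a sequence holds 2 to 5 treatments (including line 1b)")
  structure(list(lines = lines,
                 line1b = if (is.null(line1b)) NA_character_ else line1b,
                 has_line1b = !is.null(line1b),
                 label = sequence_label(lines, line1b)),
            class = "sequence_spec")
}

sequence_label <- function(lines, line1b = NULL) {
  first <- if (is.null(line1b) || is.na(line1b)) lines[1] else
    paste0(lines[1], "[", line1b, "]")
  paste(c(first, lines[-1]), collapse = "-")
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat("DMT sequence:", x$label, "\n")
  invisible(x)
}

#' @export
format.sequence_spec <- function(x, ...) x$label

# Chain line labels for a sequence of L main-chain drugs: "1a","2","3","4".
chain_labels <- function(L) c("1a", c("2", "3", "4")[seq_len(L - 1)])

#' Check one treatment switch for clinical plausibility
#'
#' A switch `from_dmt -> to_dmt` into line `position` is invalid when the
#' two drugs share a mode of action (if the rules forbid that, e.g. one
#' anti-CD20 antibody after another), when `to_dmt` is not eligible at that
#' line, or when `to_dmt` is a last-resort drug (alemtuzumab) and the
#' position is not the sequence's final line.
#'
#' @param from_dmt,to_dmt [dmt_definition()] objects.
#' @param rules A [grammar_rules()] object.
#' @param position Line label of `to_dmt` (`"1b"`, `"2"`, `"3"` or `"4"`).
#' @param is_final Whether `position` is the final line of the sequence
#'   under consideration. Defaults to `position == "4"`.
#' @return Logical flag.
#' @export
is_valid_switch <- function(from_dmt, to_dmt, rules, position,
                            is_final = identical(position, "4")) {
  stopifnot(inherits(from_dmt, "dmt_definition"),
            inherits(to_dmt, "dmt_definition"),
            position %in% LINE_LABELS)
  if (rules$forbid_same_moa_consecutive &&
      identical(from_dmt$moa_class, to_dmt$moa_class)) return(FALSE)
  if (!(position %in% to_dmt$eligible_lines)) return(FALSE)
  if (to_dmt$name %in% rules$last_resort_only && !is_final) return(FALSE)
  TRUE
}

# Is `name` allowed to open a sequence, and does it suppress line 1b?
first_line_info <- function(name, rules) {
  if (name %in% rules$first_line_highefficacy_set)
    return(list(ok = TRUE, line1b = FALSE))
  if (name %in% rules$first_line_escalation_set)
    return(list(ok = TRUE, line1b = rules$line1b_enabled))
  list(ok = FALSE, line1b = FALSE)
}

#' Enumerate all plausible sequences through an anchor drug
#'
#' Produces every valid [sequence_spec()] that places `anchor_dmt` at
#' `anchor_line`, using full-length chains (lines 1a through 4). Every
#' junction of an emitted sequence passes [is_valid_switch()]; no drug is
#' used twice (no re-treatment); sequences are returned in deterministic
#' lexicographic order of their labels. For escalation openers with
#' `line1b_enabled`, variants with each eligible line-1b drug are emitted
#' alongside the no-1b variant; high-efficacy openers never carry line 1b.
#'
#' @param anchor_dmt Name of the anchor drug.
#' @param anchor_line Line label at which it must appear
#'   (`"1a"`, `"2"`, `"3"` or `"4"`).
#' @param dmts Named list of [dmt_definition()] objects.
#' @param rules A [grammar_rules()] object.
#' @return List of `sequence_spec` objects.
#' @export
enumerate_sequences <- function(anchor_dmt, anchor_line, dmts, rules) {
  stopifnot(anchor_line %in% c("1a", "2", "3", "4"))
  if (is.null(dmts[[anchor_dmt]]))
    stop("unknown DMT name: ", anchor_dmt)
  L <- min(4L, rules$max_lines - 1L)       # main-chain length (1b excluded)
  labels <- chain_labels(L)
  anchor_pos <- match(anchor_line, labels)
  if (is.na(anchor_pos))
    stop("anchor line ", anchor_line, " outside the configured chain")
  if (anchor_line == "1a") {
    if (!first_line_info(anchor_dmt, rules)$ok)
      stop("anchor drug ", anchor_dmt, " is not eligible to open a sequence")
  } else if (!(anchor_line %in% dmts[[anchor_dmt]]$eligible_lines)) {
    stop("anchor drug ", anchor_dmt, " is not eligible at line ", anchor_line)
  }

  out <- list()
  extend <- function(chain) {
    pos <- length(chain) + 1L
    if (pos > L) {
      out[[length(out) + 1L]] <<- chain
      return(invisible())
    }
    if (pos == anchor_pos) {
      cands <- anchor_dmt
    } else {
      # the anchor is reserved for its own position; no re-treatment
      cands <- setdiff(names(dmts), c(chain, anchor_dmt))
    }
    for (nm in sort(cands)) {
      if (pos == 1L) {
        if (!first_line_info(nm, rules)$ok) next
      } else {
        ok <- is_valid_switch(dmts[[chain[pos - 1L]]], dmts[[nm]], rules,
                              labels[pos], is_final = (pos == L))
        if (!ok) next
      }
      extend(c(chain, nm))
    }
  }
  extend(character())

  specs <- list()
  for (chain in out) {
    opener <- first_line_info(chain[1], rules)
    specs[[length(specs) + 1L]] <- sequence_spec(chain)
    if (opener$line1b) {
      b_cands <- sort(setdiff(names(dmts), chain))
      for (b in b_cands) {
        if (!is_valid_switch(dmts[[chain[1]]], dmts[[b]], rules, "1b",
                             is_final = FALSE)) next
        # line 1b hands over to line 2 as well
        if (length(chain) > 1 &&
            !is_valid_switch(dmts[[b]], dmts[[chain[2]]], rules, "2",
                             is_final = (length(chain) == 2))) next
        specs[[length(specs) + 1L]] <- sequence_spec(chain, line1b = b)
      }
    }
  }
  specs <- specs[order(vapply(specs, `[[`, "", "label"))]
  specs
}

#' Tabulate enumerated sequences
#'
#' @param seqs List of [sequence_spec()] objects.
#' @return `data.frame(label, line1a, line1b, line2, line3, line4)`.
#' @export
sequences_as_table <- function(seqs) {
  get_line <- function(s, i) if (length(s$lines) >= i) s$lines[i] else NA_character_
  data.frame(
    label = vapply(seqs, `[[`, "", "label"),
    line1a = vapply(seqs, get_line, "", 1),
    line1b = vapply(seqs, `[[`, "", "line1b"),
    line2 = vapply(seqs, get_line, "", 2),
    line3 = vapply(seqs, get_line, "", 3),
    line4 = vapply(seqs, get_line, "", 4),
    stringsAsFactors = FALSE)
}

# Internal: check a sequence end-to-end against the rules (self-consistency).
sequence_is_valid <- function(seq, dmts, rules) {
  chain <- seq$lines
  L <- length(chain)
  labels <- chain_labels(L)
  if (!first_line_info(chain[1], rules)$ok) return(FALSE)
  if (anyDuplicated(c(chain, if (seq$has_line1b) seq$line1b))) return(FALSE)
  for (i in seq_len(L - 1)) {
    if (!is_valid_switch(dmts[[chain[i]]], dmts[[chain[i + 1]]], rules,
                         labels[i + 1], is_final = (i + 1 == L)))
      return(FALSE)
  }
  if (seq$has_line1b) {
    if (!first_line_info(chain[1], rules)$line1b) return(FALSE)
    if (!is_valid_switch(dmts[[chain[1]]], dmts[[seq$line1b]], rules, "1b",
                         is_final = FALSE)) return(FALSE)
    if (L > 1 && !is_valid_switch(dmts[[seq$line1b]], dmts[[chain[2]]], rules,
                                  "2", is_final = (L == 2))) return(FALSE)
  }
  TRUE
}
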