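# Structured MCNP cards.  A card is a list carrying the card text plus the
# ids it defines and references, so the deck linter can check reference
# closure without re-parsing MCNP syntax.
mcnp_card <- function(block, text, defines = list(), refs = list()) {
  structure(list(block = block, text = text, defines = defines, refs = refs),
            class = "mcnp_card")
}

mcnp_comment <- function(block, text) mcnp_card(block, paste("c", text))

# Deterministic number formatting for card fields.
fmt_num <- function(x) {
  s <- sprintf("%.10g", x)
  ifelse(s == "-0", "0", s)
}

fmt_prob <- function(x) sprintf("%.15g", x)

#' Wrap an MCNP card to the 78-character line limit
#'
#' Splits a card at token boundaries so that every emitted line is at most
#' 78 characters; continuation lines begin with 5 blanks.  Re-joining the
#' tokens of the wrapped lines reproduces the original token stream.
#'
#' @param text A single card as one string.
#' @param limit Maximum line length.
#' @return Character vector of lines.
#' @export
#' @examples
#' wrap_card("m1 1001 2 6000 1")
wrap_card <- function(text, limit = 78L) {
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(tokens) == 0L) return("")
  cont <- strrep(" ", 5L)
  if (any(nchar(tokens) > limit - 5L)) {
    bad <- tokens[which(nchar(tokens) > limit - 5L)[1]]
    bp_abort("bp_config_error", sprintf(
      "card token '%s' is longer than the %d-character card line limit",
      substr(bad, 1, 30), limit))
  }
  lines <- character(0)
  cur <- tokens[1]
  for (tok in tokens[-1]) {
    cand <- paste(cur, tok)
    if (nchar(cand) <= limit) {
      cur <- cand
    } else {
      lines <- c(lines, cur)
      cur <- paste0(cont, tok)
    }
  }
  c(lines, cur)
}

#' Assemble an MCNP deck object
#'
#' @param title Title-card text.
#' @param cards List of cards produced by the emitters.
#' @return An object of class `mcnp_deck` with ordered `cell_cards`,
#'   `surface_cards` and `data_cards`.
#' @export
mcnp_deck <- function(title, cards) {
  blocks <- vapply(cards, function(cd) cd$block, character(1))
  structure(list(title = title,
                 cell_cards = cards[blocks == "cell"],
                 surface_cards = cards[blocks == "surface"],
                 data_cards = cards[blocks == "data"]),
            class = "mcnp_deck")
}

#' @export
print.mcnp_deck <- function(x, ...) {
  cat(sprintf("<mcnp_deck> '%s': %d cell, %d surface, %d data cards\n",
              x$title, length(x$cell_cards), length(x$surface_cards),
              length(x$data_cards)))
  invisible(x)
}

#' Serialize an MCNP deck to input-file text
#'
#' Produces the canonical three-block MCNP input: title card, cell block,
#' blank line, surface block, blank line, data block.  All cards are wrapped
#' to 78 characters with 5-blank continuations; output is byte-stable for
#' identical input.
#'
#' @param deck An [mcnp_deck()].
#' @return A single string (LF line endings, trailing newline).
#' @export
serialize_deck <- function(deck) {
  block_lines <- function(cards) {
    unlist(lapply(cards, function(cd) wrap_card(cd$text)), use.names = FALSE)
  }
  lines <- c(deck$title,
             block_lines(deck$cell_cards),
             "",
             block_lines(deck$surface_cards),
             "",
             block_lines(deck$data_cards))
  paste0(paste(lines, collapse = "\n"), "\n")
}

collect_ids <- function(cards, what, field) {
  out <- unlist(lapply(cards, function(cd) cd[[what]][[field]]), use.names = FALSE)
  if (is.null(out)) integer(0) else out
}

#' Lint an MCNP deck for reference closure
#'
#' Checks that every surface, cell, universe, transform and material id
#' referenced anywhere in the deck is also defined, that no id is defined
#' twice, and that fully-specified FILL arrays carry exactly nx*ny*nz
#' entries.
#'
#' @param deck An [mcnp_deck()].
#' @return Character vector of problems; empty when the deck is clean.
#' @export
lint_deck <- function(deck) {
  cards <- c(deck$cell_cards, deck$surface_cards, deck$data_cards)
  issues <- character(0)
  for (ns in c("surface", "cell", "universe", "transform", "material")) {
    def <- collect_ids(cards, "defines", ns)
    ref <- collect_ids(cards, "refs", ns)
    dup <- unique(def[duplicated(def)])
    if (length(dup) > 0L) {
      issues <- c(issues, sprintf("%s id(s) defined more than once: %s",
                                  ns, paste(dup, collapse = ", ")))
    }
    missing <- setdiff(ref, def)
    if (length(missing) > 0L) {
      issues <- c(issues, sprintf("%s id(s) referenced but never defined: %s",
                                  ns, paste(sort(missing), collapse = ", ")))
    }
  }
  for (cd in cards) {
    if (!is.null(cd$defines$fill_n)) {
      want <- cd$defines$fill_n
      got <- cd$defines$fill_entries
      if (length(got) != want) {
        issues <- c(issues, sprintf(
          "lattice cell %d: FILL array has %d entries, expected %d",
          cd$defines$cell, length(got), want))
      }
    }
  }
  issues
}
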