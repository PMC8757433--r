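# Restricted SMARTS parsing: atomic queries are And-conjunctions of simple
# primitives (element/aromaticity, charge, H count, degree, connectivity,
# chirality). Or (","), negation ("!"), recursion ("$(") and compound
# wildcards are rejected up front; a bare "*" atom is allowed.

.ELEMENTS <- c(
  "He", "Li", "Be", "Ne", "Na", "Mg", "Al", "Si", "Cl", "Ar", "Ca", "Sc",
  "Ti", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se",
  "Br", "Kr", "Rb", "Sr", "Zr", "Nb", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Sb", "Te", "Xe", "Cs", "Ba", "Pt", "Au", "Hg", "Tl", "Pb",
  "Bi", "H", "B", "C", "N", "O", "F", "P", "S", "K", "V", "Y", "I", "W"
)

.ATOMIC_NUM <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L,
  F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Ti = 22L, V = 23L,
  Cr = 24L, Mn = 25L, Fe = 26L, Co = 27L, Ni = 28L, Cu = 29L, Zn = 30L,
  Ga = 31L, Ge = 32L, As = 33L, Se = 34L, Br = 35L, Zr = 40L, Pd = 46L,
  Ag = 47L, Cd = 48L, Sn = 50L, Sb = 51L, Te = 52L, I = 53L, Pt = 78L,
  Au = 79L, Hg = 80L, Pb = 82L, Bi = 83L
)

.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")
.BOND_CHARS <- c("-", "=", "#", ":", "~", "/", "\\")

.parse_error <- function(msg, token = NULL) {
  stop(errorCondition(
    if (is.null(token)) msg else sprintf("%s (token: \"%s\")", msg, token),
    class = c("retempl_parse_error", "error")
  ))
}

.unsupported_error <- function(token, context) {
  stop(errorCondition(
    sprintf("unsupported SMARTS query \"%s\" in \"%s\": only And-combinations of simple primitives are handled",
            token, context),
    class = c("retempl_unsupported_query", "retempl_parse_error", "error")
  ))
}

.new_atom_query <- function(symbol, aromatic = FALSE, charge = NA_integer_,
                            hcount = NA_integer_, degree = NA_integer_,
                            conn = NA_integer_, chiral = NA_character_,
                            map = 0L) {
  q <- list(symbol = symbol, aromatic = aromatic, charge = charge,
            hcount = hcount, degree = degree, conn = conn, chiral = chiral,
            map = map)
  q$key <- .serialize_atom_query(q, with_map = FALSE)
  q
}

#' Serialize an atomic query
#'
#' Emits the atomic SMARTS of a query in the package's frozen primitive order:
#' element/aromatic symbol, charge, hydrogen count, degree, connectivity,
#' chirality, then (optionally) the atom map. Because this string doubles as a
#' Weisfeiler-Lehman node feature, the order is part of the canonical form and
#' must never change.
#'
#' @param q an atom query as stored inside a parsed template
#' @param with_map include the `:n` atom-map suffix?
#' @return a single character string, e.g. `"[C;H2;+0:1]"`
#' @keywords internal
.serialize_atom_query <- function(q, with_map = TRUE) {
  sym <- if (q$symbol == "*") {
    "*"
  } else if (is.na(q$aromatic)) {
    paste0("#", .ATOMIC_NUM[[q$symbol]])
  } else if (isTRUE(q$aromatic)) {
    tolower(q$symbol)
  } else {
    q$symbol
  }
  parts <- sym
  if (!is.na(q$charge)) {
    parts <- c(parts, if (q$charge >= 0) paste0("+", q$charge)
               else paste0("-", abs(q$charge)))
  }
  if (!is.na(q$hcount)) parts <- c(parts, paste0("H", q$hcount))
  if (!is.na(q$degree)) parts <- c(parts, paste0("D", q$degree))
  if (!is.na(q$conn)) parts <- c(parts, paste0("X", q$conn))
  if (!is.na(q$chiral)) parts <- c(parts, q$chiral)
  body <- paste(parts, collapse = ";")
  if (with_map && q$map > 0L) body <- paste0(body, ":", q$map)
  paste0("[", body, "]")
}

# Consume the primitives of one bracket-atom token sequence. `content` is the
# bracket interior without the trailing :map. Primitives may be ;-separated or
# fused ("CH3+0").
.parse_bracket_atom <- function(content, map, full) {
  if (grepl(",", content, fixed = TRUE)) .unsupported_error(",", full)
  if (grepl("!", content, fixed = TRUE)) .unsupported_error("!", full)
  if (grepl("$", content, fixed = TRUE)) .unsupported_error("$(", full)
  symbol <- NULL; aromatic <- FALSE
  charge <- NA_integer_; hcount <- NA_integer_
  degree <- NA_integer_; conn <- NA_integer_; chiral <- NA_character_
  tokens <- strsplit(content, "[;&]")[[1]]
  first_tok <- TRUE
  for (tok in tokens) {
    s <- tok
    first_in_tok <- TRUE
    while (nzchar(s)) {
      if (grepl("^#\\d+", s)) {
        m <- regmatches(s, regexpr("^#\\d+", s))
        z <- as.integer(sub("#", "", m))
        hit <- names(.ATOMIC_NUM)[match(z, .ATOMIC_NUM)]
        if (is.na(hit)) .parse_error("unknown atomic number", m)
        symbol <- hit; aromatic <- NA
        s <- substr(s, nchar(m) + 1L, nchar(s))
      } else if (grepl("^\\*", s)) {
        symbol <- "*"; aromatic <- NA
        s <- substr(s, 2L, nchar(s))
      } else if (grepl("^@@?", s) && grepl("^@", s)) {
        m <- regmatches(s, regexpr("^@@?", s))
        chiral <- m
        s <- substr(s, nchar(m) + 1L, nchar(s))
      } else if (grepl("^H\\d+", s)) {
        m <- regmatches(s, regexpr("^H\\d+", s))
        hcount <- as.integer(sub("H", "", m))
        s <- substr(s, nchar(m) + 1L, nchar(s))
      } else if (grepl("^H", s) && is.null(symbol) && first_tok && first_in_tok &&
                 !grepl("^H[a-z]", s)) {
        symbol <- "H"  # [H] / [H+]: an actual hydrogen atom
        s <- substr(s, 2L, nchar(s))
      } else if (grepl("^H", s) && !grepl("^H[a-z]", s)) {
        hcount <- 1L
        s <- substr(s, 2L, nchar(s))
      } else if (grepl("^D\\d+", s)) {
        m <- regmatches(s, regexpr("^D\\d+", s))
        degree <- as.integer(sub("D", "", m))
        s <- substr(s, nchar(m) + 1L, nchar(s))
      } else if (grepl("^X\\d+", s)) {
        m <- regmatches(s, regexpr("^X\\d+", s))
        conn <- as.integer(sub("X", "", m))
        s <- substr(s, nchar(m) + 1L, nchar(s))
      } else if (grepl("^[+-]", s)) {
        m <- regmatches(s, regexpr("^(\\+\\d+|-\\d+|\\++|-+)", s))
        sign <- if (substr(m, 1L, 1L) == "+") 1L else -1L
        mag <- if (grepl("\\d", m)) as.integer(gsub("[+-]", "", m))
               else nchar(m)
        charge <- sign * mag
        s <- substr(s, nchar(m) + 1L, nchar(s))
      } else if (grepl("^[A-Z][a-z]?", s)) {
        two <- substr(s, 1L, 2L)
        one <- substr(s, 1L, 1L)
        m <- if (two %in% .ELEMENTS) two
             else if (one %in% .ELEMENTS) one
             else .parse_error("unknown element symbol in bracket atom", s)
        if (!is.null(symbol)) .parse_error("second element primitive in one atom", full)
        symbol <- m; aromatic <- FALSE
        s <- substr(s, nchar(m) + 1L, nchar(s))
      } else if (grepl("^[bcnosp]", s)) {
        if (!is.null(symbol)) .parse_error("second element primitive in one atom", full)
        symbol <- toupper(substr(s, 1L, 1L)); aromatic <- TRUE
        s <- substr(s, 2L, nchar(s))
      } else {
        .unsupported_error(s, full)
      }
      first_in_tok <- FALSE
    }
    first_tok <- FALSE
  }
  if (is.null(symbol)) .parse_error("bracket atom lacks an element primitive", full)
  .new_atom_query(symbol, aromatic, charge, hcount, degree, conn, chiral, map)
}

# Memoized bracket-atom parsing: the same query body (map stripped) recurs
# constantly across a corpus, so parse once and stamp the map on afterwards.
.QUERY_CACHE <- new.env(parent = emptyenv())

.parse_bracket_cached <- function(content, map, full) {
  q <- .QUERY_CACHE[[content]]
  if (is.null(q)) {
    q <- .parse_bracket_atom(content, 0L, full)
    .QUERY_CACHE[[content]] <- q
  }
  if (map > 0L) q$map <- map
  q
}

.BARE_CACHE <- new.env(parent = emptyenv())

.bare_atom_cached <- function(symbol, aromatic) {
  key <- paste0(symbol, if (isTRUE(aromatic)) "a" else if (is.na(aromatic)) "?" else "A")
  q <- .BARE_CACHE[[key]]
  if (is.null(q)) {
    q <- .new_atom_query(symbol, aromatic = aromatic)
    .BARE_CACHE[[key]] <- q
  }
  q
}

.FRAG_TOKEN_RE <- "\\[[^]]*\\]|%\\d{2}|Cl|Br|[()]|[-=#:~/\\\\]|\\d|[A-Za-z*]"

# Parse one dot-free SMARTS/SMILES fragment into atoms + bonds (1-based atom
# indices local to the fragment). Shared by the template and molecule parsers.
.parse_fragment <- function(frag) {
  atoms <- list()
  bonds <- list()          # list of c(i, j, bond-string)
  ring_open <- list()      # closure digit -> list(atom, bond)
  prev_stack <- integer(0) # branch stack
  prev <- 0L
  pending_bond <- NA_character_
  add_bond <- function(a, b, bond) {
    bonds[[length(bonds) + 1L]] <<- list(i = min(a, b), j = max(a, b), b = bond)
  }
  implicit_bond <- function(a, b) {
    if (isTRUE(atoms[[a]]$aromatic) && isTRUE(atoms[[b]]$aromatic)) ":" else "-"
  }
  new_atom <- function(q) {
    atoms[[length(atoms) + 1L]] <<- q
    idx <- length(atoms)
    if (prev > 0L) {
      bond <- if (is.na(pending_bond)) implicit_bond(prev, idx) else pending_bond
      add_bond(prev, idx, bond)
    }
    prev <<- idx
    pending_bond <<- NA_character_
    idx
  }
  if (grepl(",", frag, fixed = TRUE)) .unsupported_error(",", frag)
  if (grepl("!", frag, fixed = TRUE)) .unsupported_error("!", frag)
  toks <- regmatches(frag, gregexpr(.FRAG_TOKEN_RE, frag, perl = TRUE))[[1]]
  if (sum(nchar(toks)) != nchar(frag))
    .parse_error("unexpected character in fragment", frag)
  for (tok in toks) {
    first <- substr(tok, 1L, 1L)
    if (first == "[") {
      content <- substr(tok, 2L, nchar(tok) - 1L)
      map <- 0L
      mm <- regexpr(":(\\d+)$", content)
      if (mm > 0) {
        map <- as.integer(substr(content, mm + 1L, nchar(content)))
        content <- substr(content, 1L, mm - 1L)
      }
      new_atom(.parse_bracket_cached(content, map, tok))
    } else if (tok %in% .BOND_CHARS) {
      pending_bond <- tok
    } else if (tok == "(") {
      prev_stack <- c(prev_stack, prev)
    } else if (tok == ")") {
      if (length(prev_stack) == 0L) .parse_error("unbalanced parenthesis", frag)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
    } else if (first == "%" || (first >= "0" && first <= "9")) {
      num <- if (first == "%") substr(tok, 2L, 3L) else tok
      if (prev == 0L) .parse_error("ring closure before any atom", frag)
      key <- as.character(as.integer(num))
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        bond <- if (!is.na(pending_bond)) pending_bond
                else if (!is.na(op$bond)) op$bond
                else implicit_bond(op$atom, prev)
        add_bond(op$atom, prev, bond)
        ring_open[[key]] <- NULL
      } else {
        ring_open[[key]] <- list(atom = prev, bond = pending_bond)
      }
      pending_bond <- NA_character_
    } else if (tok %in% .AROMATIC_ORGANIC) {
      new_atom(.bare_atom_cached(toupper(tok), TRUE))
    } else if (tok == "*") {
      new_atom(.bare_atom_cached("*", NA))
    } else if (tok %in% c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")) {
      new_atom(.bare_atom_cached(tok, FALSE))
    } else {
      .parse_error(sprintf("unexpected token \"%s\"", tok), frag)
    }
  }
  if (length(ring_open) > 0L) .parse_error("unclosed ring bond", frag)
  if (length(prev_stack) > 0L) .parse_error("unbalanced parenthesis", frag)
  if (length(atoms) == 0L) .parse_error("empty fragment", frag)
  list(atoms = atoms, bonds = bonds)
}

# Parse one side of a template (dot-separated fragments) into a side graph:
# atoms (queries), bonds data.frame (i, j, b), frag (fragment id per atom).
.parse_side <- function(s) {
  frags <- strsplit(s, ".", fixed = TRUE)[[1]]
  if (length(frags) == 0L || any(!nzchar(frags)))
    .parse_error("empty fragment on one template side", s)
  atoms <- list()
  bi <- integer(0); bj <- integer(0); bb <- character(0)
  fragid <- integer(0)
  for (k in seq_along(frags)) {
    fr <- .parse_fragment(frags[k])
    off <- length(atoms)
    atoms <- c(atoms, fr$atoms)
    fragid <- c(fragid, rep.int(k, length(fr$atoms)))
    if (length(fr$bonds) > 0L) {
      bi <- c(bi, vapply(fr$bonds, function(b) b$i + off, integer(1)))
      bj <- c(bj, vapply(fr$bonds, function(b) b$j + off, integer(1)))
      bb <- c(bb, vapply(fr$bonds, function(b) b$b, character(1)))
    }
  }
  list(atoms = atoms,
       bonds = data.frame(i = bi, j = bj, b = bb),
       frag = fragid)
}

.side_maps <- function(side) {
  vapply(side$atoms, function(a) a$map, integer(1))
}

#' Parse a reaction-template record
#'
#' Parses a reaction-SMARTS template string (two sides separated by `>>`,
#' fragments separated by `.`) into a validated `rxn_template` object. Only
#' And-combinations of simple atomic primitives are accepted; Or, negation,
#' recursive SMARTS and compound wildcards raise a
#' `retempl_unsupported_query` error naming the offending token.
#'
#' For retro templates the left-hand side is the product pattern that the
#' template is matched against and the right-hand side the precursors it
#' produces; forward templates are the reverse reading.
#'
#' @param string the template as reaction SMARTS, e.g.
#'   `"[C:1](=[O:2])[O:3][C:4]>>[O]-[C:1](=[O:2]).[O:3]-[C:4]"`
#' @param direction `"retro"` (default) or `"forward"`
#' @param radius_tag one of `"r0"`, `"r1"`, `"r2"`, `"r3"`, `"default"`, or
#'   `NA` when the extraction radius is unknown
#' @param reaction_ids character vector of provenance reaction identifiers
#' @return an object of class `rxn_template` with elements `lhs`, `rhs`
#'   (side graphs), `direction`, `radius_tag`, `reaction_ids`, `raw_string`
#' @examples
#' t <- parse_template("[C:1](=[O:2])[O:3][C:4]>>[O][C:1]=[O:2].[O:3][C:4]")
#' length(t$lhs$atoms)
#' @export
parse_template <- function(string, direction = "retro",
                           radius_tag = NA_character_,
                           reaction_ids = character(0)) {
  stopifnot(is.character(string), length(string) == 1L)
  direction <- match.arg(direction, c("retro", "forward"))
  if (!is.na(radius_tag))
    radius_tag <- match.arg(radius_tag, c("r0", "r1", "r2", "r3", "default"))
  sides <- strsplit(string, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    .parse_error("template must contain exactly one \">>\" side separator", string)
  lhs <- .parse_side(sides[1])
  rhs <- .parse_side(sides[2])
  for (side in list(lhs, rhs)) {
    mp <- .side_maps(side)
    mp <- mp[mp > 0L]
    if (anyDuplicated(mp))
      .parse_error(sprintf("duplicate atom map %d within one side",
                           mp[duplicated(mp)][1]), string)
  }
  lm <- .side_maps(lhs); rm_ <- .side_maps(rhs)
  orphan <- setdiff(rm_[rm_ > 0L], lm[lm > 0L])
  if (length(orphan) > 0L)
    warning(sprintf("template has rhs-only mapped atoms (maps: %s)",
                    paste(orphan, collapse = ",")),
            call. = FALSE)
  structure(list(lhs = lhs, rhs = rhs, direction = direction,
                 radius_tag = radius_tag,
                 reaction_ids = as.character(reaction_ids),
                 raw_string = string),
            class = "rxn_template")
}

#' @export
print.rxn_template <- function(x, ...) {
  cat("<rxn_template> ", x$direction,
      if (!is.na(x$radius_tag)) paste0(" [", x$radius_tag, "]") else "",
      "\n  ", x$raw_string, "\n  reactions: ", length(x$reaction_ids),
      "\n", sep = "")
  invisible(x)
}
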