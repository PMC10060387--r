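# Minimal SMILES reader: enough structure perception for validation and
# path-based fingerprinting (atoms, bonds, branches, ring closures,
# aromatic lower-case atoms, bracket atoms with charge/H-count/isotope).
# No stereochemistry (tandem MS cannot resolve stereoisomers anyway) and no
# aromaticity perception beyond the input's own lower-case notation.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles SMILES string.
#' @return list with `atoms` (data.frame: symbol, aromatic, charge, hcount,
#'   isotope) and `bonds` (data.frame: from, to, order; order 1.5 denotes
#'   an aromatic bond). Atom indices are 1-based in input order.
#' @export
parse_smiles <- function(smiles) {
  .assert(is.character(smiles) && length(smiles) == 1 && !is.na(smiles),
          "smiles must be a single string")
  s <- trimws(smiles)
  if (!nzchar(s)) stop("cannot parse SMILES: empty string", call. = FALSE)
  fail <- function(why) stop(sprintf("cannot parse SMILES '%s': %s",
                                     smiles, why), call. = FALSE)

  sym <- character(0); arom <- logical(0); chg <- integer(0)
  hct <- integer(0); iso <- integer(0)
  b_from <- integer(0); b_to <- integer(0); b_ord <- numeric(0)

  add_atom <- function(symbol, aromatic, charge = 0L, h = NA_integer_,
                       isotope = NA_integer_) {
    sym <<- c(sym, symbol); arom <<- c(arom, aromatic)
    chg <<- c(chg, charge); hct <<- c(hct, h); iso <<- c(iso, isotope)
    length(sym)
  }
  add_bond <- function(a, b, ord) {
    b_from <<- c(b_from, a); b_to <<- c(b_to, b); b_ord <<- c(b_ord, ord)
  }

  i <- 1L; n <- nchar(s)
  prev <- 0L                       # atom awaiting a bond
  pending_bond <- NA_real_         # explicit bond symbol seen
  stack <- integer(0)              # branch stack
  rings <- list()                  # ring-closure label -> c(atom, bond)

  bond_order <- function(ch) switch(ch, "-" = 1, "=" = 2, "#" = 3,
                                    "$" = 4, ":" = 1.5, "/" = 1, "\\" = 1,
                                    NA_real_)
  connect <- function(idx) {
    if (prev > 0L) {
      ord <- pending_bond
      if (is.na(ord)) ord <- if (arom[prev] && arom[idx]) 1.5 else 1
      add_bond(prev, idx, ord)
    }
    prev <<- idx
    pending_bond <<- NA_real_
  }

  while (i <= n) {
    ch <- substr(s, i, i)
    two <- substr(s, i, i + 1L)
    if (ch == "(") {
      if (prev == 0L) fail("branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) fail("unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L; pending_bond <- NA_real_; i <- i + 1L
    } else if (!is.na(bond_order(ch))) {
      pending_bond <- bond_order(ch); i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (prev == 0L) fail("ring closure before any atom")
      if (ch == "%") {
        lab <- substr(s, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", lab)) fail("bad %nn ring label")
        i <- i + 3L
      } else {
        lab <- ch; i <- i + 1L
      }
      if (is.null(rings[[lab]])) {
        rings[[lab]] <- list(atom = prev, bond = pending_bond)
      } else {
        opened <- rings[[lab]]
        ord <- pending_bond
        if (is.na(ord)) ord <- opened$bond
        if (is.na(ord)) ord <- if (arom[opened$atom] && arom[prev]) 1.5 else 1
        if (opened$atom == prev) fail("ring bond to self")
        add_bond(opened$atom, prev, ord)
        rings[[lab]] <- NULL
      }
      pending_bond <- NA_real_
    } else if (ch == "[") {
      close_i <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (close_i < 0) fail("unmatched '['")
      body <- substr(s, i + 1L, i + close_i - 2L)
      m <- regexec(
        "^([0-9]*)(Cl|Br|[A-Z][a-z]?|[a-z]|\\*)(@{0,2})(H[0-9]*)?([+-][0-9]*|\\+{2,}|-{2,})?(:[0-9]+)?$",
        body)[[1]]
      if (m[1] < 0) fail(paste0("bad bracket atom [", body, "]"))
      part <- regmatches(body, regexec(
        "^([0-9]*)(Cl|Br|[A-Z][a-z]?|[a-z]|\\*)(@{0,2})(H[0-9]*)?([+-][0-9]*|\\+{2,}|-{2,})?(:[0-9]+)?$",
        body))[[1]]
      el <- part[3]
      aromatic <- grepl("^[a-z]$", el) && el %in% .AROMATIC_SUBSET
      if (grepl("^[a-z]$", el) && !aromatic && el != "*")
        fail(paste0("unknown aromatic element '", el, "'"))
      hpart <- part[5]
      h <- if (!nzchar(hpart)) 0L
           else if (hpart == "H") 1L else as.integer(substr(hpart, 2, 10))
      cpart <- part[6]
      charge <- 0L
      if (nzchar(cpart)) {
        if (grepl("^\\++$", cpart)) charge <- nchar(cpart)
        else if (grepl("^-+$", cpart)) charge <- -nchar(cpart)
        else charge <- as.integer(paste0(substr(cpart, 1, 1),
                                         ifelse(nchar(cpart) > 1,
                                                substr(cpart, 2, 10), "1")))
      }
      isotope <- if (nzchar(part[2])) as.integer(part[2]) else NA_integer_
      symbol <- if (aromatic) toupper(el) else el
      idx <- add_atom(symbol, aromatic, charge, h, isotope)
      connect(idx)
      i <- i + close_i
    } else if (two %in% c("Cl", "Br")) {
      idx <- add_atom(two, FALSE); connect(idx); i <- i + 2L
    } else if (ch %in% .ORGANIC_SUBSET) {
      idx <- add_atom(ch, FALSE); connect(idx); i <- i + 1L
    } else if (ch %in% .AROMATIC_SUBSET) {
      idx <- add_atom(toupper(ch), TRUE); connect(idx); i <- i + 1L
    } else {
      fail(paste0("unexpected character '", ch, "' at position ", i))
    }
  }
  if (length(stack)) fail("unmatched '('")
  if (length(rings)) fail("unclosed ring bond")
  if (!length(sym)) fail("no atoms")
  list(atoms = data.frame(symbol = sym, aromatic = arom, charge = chg,
                          hcount = hct, isotope = iso,
                          stringsAsFactors = FALSE),
       bonds = data.frame(from = b_from, to = b_to, order = b_ord))
}
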