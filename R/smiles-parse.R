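# SMILES line-notation parser.
#
# Supports the organic subset (B C N O P S F Cl Br I), bracket atoms with
# explicit hydrogen counts, charges (parsed, then normalized to neutral --
# the graph model is topological and charge-free), isotopes and stereo
# marks (ignored), branches, ring-bond digits including %nn, dot-separated
# components, and aromatic lower-case notation which is kekulized to
# alternating bond orders via a perfect-matching search.

.smiles_error <- function(s, pos, msg) {
  stop(sprintf("SMILES parse error at position %d ('%s') in \"%s\": %s",
               pos, substr(s, pos, pos), s, msg), call. = FALSE)
}

# Aromatic default valences used during kekulization.
.AROM_VAL <- c(c = 4L, n = 3L, o = 2L, s = 2L, p = 3L, b = 3L)

.parse_smiles_tokens <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  np <- length(chars)
  elem <- character(0); arom <- logical(0); hexp <- integer(0)
  comp <- integer(0)                       # dot-component id per atom
  bonds <- list()                          # c(i, j, type); type 0 = unspec,
                                           # 1..3 explicit, 4 = ':'
  prev <- NA_integer_
  pending <- NA_integer_                   # bond type for next bond
  stack <- integer(0)
  rings <- list()                          # digit -> c(atom, type)
  comp_id <- 1L

  add_atom <- function(sym, aromatic, h, pos) {
    elem[length(elem) + 1L] <<- sym
    arom[length(arom) + 1L] <<- aromatic
    hexp[length(hexp) + 1L] <<- h
    comp[length(comp) + 1L] <<- comp_id
    a <- length(elem)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- c(prev, a,
                                        if (is.na(pending)) 0L else pending)
    }
    prev <<- a
    pending <<- NA_integer_
    invisible(a)
  }

  p <- 1L
  while (p <= np) {
    ch <- chars[p]
    if (ch %in% c("C", "N", "O", "P", "S", "F", "B", "I")) {
      sym <- ch
      if (ch == "C" && p < np && chars[p + 1L] == "l") { sym <- "Cl"; p <- p + 1L }
      if (ch == "B" && p < np && chars[p + 1L] == "r") { sym <- "Br"; p <- p + 1L }
      if (ch == "S" && p < np && chars[p + 1L] == "i") {
        .smiles_error(s, p, "Si must be written in brackets: [SiH4] etc.")
      }
      add_atom(sym, FALSE, NA_integer_, p)
    } else if (ch %in% c("c", "n", "o", "s", "p", "b")) {
      add_atom(toupper(ch), TRUE, NA_integer_, p)
    } else if (ch == "[") {
      close <- p + 1L
      while (close <= np && chars[close] != "]") close <- close + 1L
      if (close > np) .smiles_error(s, p, "unclosed bracket atom")
      inner <- substr(s, p + 1L, close - 1L)
      m <- regmatches(inner, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?(:[0-9]+)?$",
        inner))[[1L]]
      if (length(m) == 0L)
        .smiles_error(s, p, paste0("cannot parse bracket atom [", inner, "]"))
      sym <- m[3L]
      aromatic <- sym %in% names(.AROM_VAL)
      if (aromatic) sym <- paste0(toupper(substr(sym, 1, 1)),
                                  substr(sym, 2, nchar(sym)))
      if (!sym %in% .UB_ELEMENTS)
        .smiles_error(s, p, paste0("unknown element '", sym, "'"))
      h <- 0L
      if (m[5L] != "") {
        hh <- sub("^H", "", m[5L])
        h <- if (hh == "") 1L else as.integer(hh)
      }
      add_atom(sym, aromatic, h, p)
      p <- close
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending <- switch(ch, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 4L)
    } else if (ch == "/" || ch == "\\") {
      pending <- 1L                        # stereo bonds read as single
    } else if (ch == "(") {
      if (is.na(prev)) .smiles_error(s, p, "branch before any atom")
      stack <- c(stack, prev)
    } else if (ch == ")") {
      if (length(stack) == 0L) .smiles_error(s, p, "unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (p + 2L > np) .smiles_error(s, p, "truncated %nn ring bond")
        d <- substr(s, p + 1L, p + 2L)
        if (!grepl("^[0-9]{2}$", d)) .smiles_error(s, p, "bad %nn ring bond")
        p <- p + 2L
      } else d <- ch
      if (is.na(prev)) .smiles_error(s, p, "ring bond before any atom")
      key <- as.character(as.integer(d))
      bt <- if (is.na(pending)) 0L else pending
      pending <- NA_integer_
      if (is.null(rings[[key]])) {
        rings[[key]] <- c(prev, bt)
      } else {
        op <- rings[[key]]
        if (op[2L] != 0L && bt != 0L && op[2L] != bt)
          .smiles_error(s, p, "conflicting ring-bond orders")
        ty <- max(op[2L], bt)
        if (op[1L] == prev) .smiles_error(s, p, "ring bond to same atom")
        bonds[[length(bonds) + 1L]] <- c(op[1L], prev, ty)
        rings[[key]] <- NULL
      }
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- NA_integer_
      comp_id <- comp_id + 1L
    } else if (ch == " " || ch == "\t") {
      break                                # trailing title/id field
    } else {
      .smiles_error(s, p, "unexpected character")
    }
    p <- p + 1L
  }
  if (length(stack) > 0L) stop("SMILES parse error in \"", s,
                               "\": unbalanced '('", call. = FALSE)
  if (length(rings) > 0L) stop("SMILES parse error in \"", s,
                               "\": unclosed ring bond(s) ",
                               paste(names(rings), collapse = ", "),
                               call. = FALSE)
  if (length(elem) == 0L) stop("SMILES parse error: no atoms in \"", s, "\"",
                               call. = FALSE)
  list(elem = elem, arom = arom, hexp = hexp, comp = comp,
       bonds = do.call(rbind, c(bonds, list(matrix(integer(0), 0L, 3L)))))
}

# Resolve aromatic rings to alternating single/double bonds. Each aromatic
# atom needing one more valence unit must be paired with a neighbour along
# an aromatic bond; the pairing is found by backtracking.
.kekulize <- function(tk, s) {
  b <- tk$bonds
  arom_bond <- rep(FALSE, nrow(b))
  if (nrow(b) > 0L) {
    arom_bond <- b[, 3L] == 4L |
      (b[, 3L] == 0L & tk$arom[b[, 1L]] & tk$arom[b[, 2L]])
  }
  order <- ifelse(b[, 3L] %in% 1:3, b[, 3L], 1L)

  if (any(tk$arom)) {
    deg <- integer(length(tk$elem))
    consum <- integer(length(tk$elem))     # connection sum (orders, arom = 1)
    if (nrow(b) > 0L) {
      for (r in seq_len(nrow(b))) {
        o <- if (arom_bond[r]) 1L else order[r]
        for (endp in b[r, 1:2]) {
          deg[endp] <- deg[endp] + 1L
          consum[endp] <- consum[endp] + o
        }
      }
    }
    needs <- rep(FALSE, length(tk$elem))
    for (a in which(tk$arom)) {
      sym <- tolower(tk$elem[a])
      dv <- .AROM_VAL[[sym]]
      if (is.null(dv)) stop("cannot kekulize atom ", a, " in \"", s, "\"",
                            call. = FALSE)
      h <- tk$hexp[a]
      if (is.na(h)) h <- if (sym == "c") max(0L, 3L - deg[a]) else 0L
      need <- dv - consum[a] - h
      if (need < 0L || need > 1L)
        stop("cannot kekulize \"", s, "\": aromatic atom ", a,
             " needs ", need, " extra bond(s)", call. = FALSE)
      needs[a] <- need == 1L
    }
    # perfect matching on needing atoms along aromatic bonds
    ab <- which(arom_bond)
    nbr <- lapply(seq_along(tk$elem), function(a) integer(0))
    for (r in ab) {
      i <- b[r, 1L]; j <- b[r, 2L]
      if (needs[i] && needs[j]) {
        nbr[[i]] <- c(nbr[[i]], r)
        nbr[[j]] <- c(nbr[[j]], r)
      }
    }
    matched <- rep(FALSE, length(tk$elem))
    double <- rep(FALSE, nrow(b))
    solve <- function(todo) {
      todo <- todo[!matched[todo]]
      if (length(todo) == 0L) return(TRUE)
      a <- todo[1L]
      for (r in nbr[[a]]) {
        other <- setdiff(b[r, 1:2], a)
        if (matched[other]) next
        matched[a] <<- TRUE; matched[other] <<- TRUE; double[r] <<- TRUE
        if (solve(todo[-1L])) return(TRUE)
        matched[a] <<- FALSE; matched[other] <<- FALSE; double[r] <<- FALSE
      }
      FALSE
    }
    if (!solve(which(needs)))
      stop("cannot kekulize \"", s, "\": no alternating bond assignment",
           call. = FALSE)
    order[double] <- 2L
  }
  order
}

# Parse one SMILES string into a list of connected molgraph components.
.parse_smiles_components <- function(s) {
  s <- trimws(s)
  tk <- .parse_smiles_tokens(s)
  order <- .kekulize(tk, s)
  b <- tk$bonds
  elem <- tk$elem

  # drop explicit hydrogen atoms (hydrogen-suppressed graph)
  keepa <- elem != "H"
  if (!all(keepa)) {
    if (!any(keepa)) stop("molecule \"", s, "\" has no heavy atoms",
                          call. = FALSE)
    idx <- cumsum(keepa)
    if (nrow(b) > 0L) {
      keepb <- keepa[b[, 1L]] & keepa[b[, 2L]]
      b <- b[keepb, , drop = FALSE]
      order <- order[keepb]
      b[, 1L] <- idx[b[, 1L]]
      b[, 2L] <- idx[b[, 2L]]
    }
    elem <- elem[keepa]
    hx <- tk$hexp[keepa]
  } else hx <- tk$hexp

  bond <- cbind(b[, 1:2, drop = FALSE], order)
  g <- molgraph(elem, bond, validate = FALSE)

  # valence check with explicit hydrogens honoured
  bs <- bond_order_sums(g)
  for (a in seq_along(elem)) {
    maxv <- .elem_max_valence(elem[a])
    ha <- if (is.na(hx[a])) 0L else hx[a]
    if (bs[a] + ha > maxv)
      stop("valence violation in \"", s, "\" at atom index ", a, " (",
           elem[a], ", bond order sum ", bs[a] + ha, " > ", maxv, ")",
           call. = FALSE)
  }
  comps <- .components(g)
  lapply(comps, function(at) .subgraph_atoms(g, at))
}

#' Parse a structure from SMILES or a MOL block
#'
#' `parse_structure()` accepts either a SMILES string or an MDL MOL block
#' (auto-detected) and returns a [molgraph]. Aromatic SMILES input is
#' kekulized to alternating bond orders; charges and stereochemistry are
#' normalized away (the model is 2-D topological and neutral).
#'
#' @param text A SMILES string or MOL block.
#' @param component How to treat multi-component (dot-separated) input:
#'   `"error"` (default) rejects it, `"largest"` keeps the component with
#'   most heavy atoms (ties broken by canonical SMILES order), `"all"`
#'   returns a list of components.
#' @return A [molgraph], or a list of them when `component = "all"`.
#' @export
parse_structure <- function(text, component = c("error", "largest", "all")) {
  component <- match.arg(component)
  if (grepl("\n", text) && grepl("V2000|M  END", text)) {
    return(parse_molblock(text, component = component))
  }
  parse_smiles(text, component = component)
}

#' @rdname parse_structure
#' @export
parse_smiles <- function(text, component = c("error", "largest", "all")) {
  component <- match.arg(component)
  stopifnot(is.character(text), length(text) == 1L)
  comps <- .parse_smiles_components(text)
  .pick_component(comps, component, text)
}

.pick_component <- function(comps, component, text) {
  if (length(comps) == 1L && component != "all") return(comps[[1L]])
  switch(component,
    error = stop("structure \"", text, "\" has ", length(comps),
                 " disconnected components; use component = \"largest\" ",
                 "or \"all\"", call. = FALSE),
    largest = {
      sz <- vapply(comps, heavy_atoms, integer(1))
      best <- which(sz == max(sz))
      if (length(best) > 1L) {
        cs <- vapply(comps[best], mol_to_smiles, character(1))
        best <- best[order(cs)][1L]
      }
      comps[[best]]
    },
    all = comps
  )
}
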