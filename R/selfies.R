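# SELFIES codec for the neutral organic subset.
#
# The decoder is a derivation-rule state machine: every token either attaches
# an atom (with its bond order capped by the remaining valence of the current
# atom), opens a fixed-length branch, or closes a ring to an earlier atom.
# Tokens that cannot be applied are skipped, so EVERY sequence over the
# alphabet decodes to a valid molecule (the 100%-robustness property that
# makes the generator's Valid metric exactly 1).

# element valence caps (maximum explicit bond order sum)
.mg_valence <- c(B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, P = 5L, S = 6L,
                 Cl = 1L, Br = 1L, I = 1L)

.mg_bond_char <- c("", "=", "#")

.mg_atom_tokens <- local({
  out <- character()
  for (el in names(.mg_valence)) {
    for (o in seq_len(min(3L, .mg_valence[[el]]))) {
      out <- c(out, paste0("[", .mg_bond_char[o], el, "]"))
    }
  }
  out
})

.mg_struct_tokens <- c("[Branch1]", "[Branch2]",
                       "[Ring1]", "[Ring2]",
                       "[=Ring1]", "[=Ring2]",
                       "[#Ring1]", "[#Ring2]")

# fixed 16-token index alphabet: a token following Branch/Ring symbols is
# read as a base-16 digit through this table (unlisted tokens read as 0)
.mg_index_alphabet <- c("[C]", "[Ring1]", "[Ring2]", "[Branch1]", "[Branch2]",
                        "[=C]", "[#C]", "[N]", "[=N]", "[O]", "[=O]",
                        "[S]", "[P]", "[F]", "[Cl]", "[Br]")

#' The SELFIES chemical token alphabet
#'
#' All chemical tokens the codec understands: atom tokens over the neutral
#' organic subset (B, C, N, O, F, P, S, Cl, Br, I) with single/double/triple
#' bond prefixes capped by element valence, plus branch and ring tokens.
#' Special tokens (SOS/EOS/PAD) are not part of this alphabet; they are added
#' by [build_vocabulary()].
#'
#' @param atoms_only If `TRUE`, return only atom tokens (no branch/ring
#'   symbols).
#' @return Character vector of bracketed tokens.
#' @export
selfies_alphabet <- function(atoms_only = FALSE) {
  if (atoms_only) .mg_atom_tokens else c(.mg_atom_tokens, .mg_struct_tokens)
}

#' Split a SELFIES string into tokens
#'
#' @param selfies A single SELFIES string, e.g. `"[C][C][O]"`.
#' @return Character vector of bracketed tokens (`character(0)` for `""`).
#' @export
split_selfies <- function(selfies) {
  stopifnot(is.character(selfies), length(selfies) == 1L)
  if (is.na(selfies) || selfies == "") return(character())
  toks <- regmatches(selfies, gregexpr("\\[[^][]*\\]", selfies))[[1]]
  if (paste(toks, collapse = "") != selfies) {
    stop("malformed SELFIES string (text outside bracketed tokens): ", selfies)
  }
  toks
}

.mg_parse_atom_token <- function(tok) {
  inner <- substr(tok, 2L, nchar(tok) - 1L)
  order <- 1L
  if (startsWith(inner, "=")) {
    order <- 2L; inner <- substring(inner, 2L)
  } else if (startsWith(inner, "#")) {
    order <- 3L; inner <- substring(inner, 2L)
  }
  if (!inner %in% names(.mg_valence)) return(NULL)
  if (order > .mg_valence[[inner]]) return(NULL)
  list(element = inner, order = order)
}

.mg_index_value <- function(tok) {
  i <- match(tok, .mg_index_alphabet)
  if (is.na(i)) 0L else i - 1L
}

# --- decoder -----------------------------------------------------------------

# mutable molecule state during derivation
.mg_new_state <- function() {
  env <- new.env(parent = emptyenv())
  env$element <- character()
  env$cap <- integer()
  env$used <- integer()
  env$bonds <- list() # list of c(i, j, order)
  env
}

.mg_add_atom <- function(st, element) {
  st$element <- c(st$element, element)
  st$cap <- c(st$cap, .mg_valence[[element]])
  st$used <- c(st$used, 0L)
  length(st$element)
}

.mg_add_bond <- function(st, i, j, order) {
  st$bonds[[length(st$bonds) + 1L]] <- c(i, j, order)
  st$used[i] <- st$used[i] + order
  st$used[j] <- st$used[j] + order
}

.mg_has_bond <- function(st, i, j) {
  any(vapply(st$bonds, function(b) {
    (b[1] == i && b[2] == j) || (b[1] == j && b[2] == i)
  }, logical(1)))
}

# derive `tokens` attached to atom `cur` (0 = no atom yet); returns invisibly
.mg_derive <- function(tokens, st, cur) {
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    tok <- tokens[i]
    atom <- .mg_parse_atom_token(tok)
    if (!is.null(atom)) {
      if (cur == 0L) {
        cur <- .mg_add_atom(st, atom$element)
      } else if (st$cap[cur] - st$used[cur] >= 1L) {
        o <- min(atom$order, st$cap[cur] - st$used[cur],
                 .mg_valence[[atom$element]])
        new <- .mg_add_atom(st, atom$element)
        .mg_add_bond(st, cur, new, o)
        cur <- new
      } # else: saturated current atom, token skipped
      i <- i + 1L
    } else if (tok %in% c("[Branch1]", "[Branch2]")) {
      nidx <- if (tok == "[Branch1]") 1L else 2L
      if (i + nidx > n) break # truncated index, ignore tail
      q <- 0L
      for (k in seq_len(nidx)) q <- q * 16L + .mg_index_value(tokens[i + k])
      len <- q + 1L
      content <- tokens[seq.int(i + nidx + 1L,
                                length.out = min(len, max(0L, n - i - nidx)))]
      i <- i + nidx + length(content) + 1L
      if (cur != 0L && st$cap[cur] - st$used[cur] >= 1L &&
          length(content) > 0L) {
        .mg_derive(content, st, cur)
      }
    } else if (grepl("Ring[12]\\]$", tok)) {
      order <- if (startsWith(tok, "[=")) 2L
               else if (startsWith(tok, "[#")) 3L else 1L
      nidx <- if (endsWith(tok, "1]")) 1L else 2L
      if (i + nidx > n) break
      q <- 0L
      for (k in seq_len(nidx)) q <- q * 16L + .mg_index_value(tokens[i + k])
      i <- i + nidx + 1L
      if (cur != 0L) {
        target <- cur - (q + 1L)
        if (target >= 1L && target != cur && !.mg_has_bond(st, cur, target)) {
          o <- min(order, st$cap[cur] - st$used[cur],
                   st$cap[target] - st$used[target])
          if (o >= 1L) .mg_add_bond(st, cur, target, o)
        }
      }
    } else {
      stop("token not in the SELFIES alphabet: ", tok)
    }
  }
  invisible(cur)
}

# --- graph -> SMILES writer --------------------------------------------------

.mg_write_smiles <- function(element, bonds) {
  n <- length(element)
  if (n == 0L) return("")
  adj <- vector("list", n)
  for (b in bonds) {
    adj[[b[1]]] <- rbind(adj[[b[1]]], c(b[2], b[3]))
    adj[[b[2]]] <- rbind(adj[[b[2]]], c(b[1], b[3]))
  }
  visited <- logical(n)
  ring_digit <- 0L
  # open ring digits per atom: list of c(digit, order) to print at that atom
  open_at <- vector("list", n)
  close_at <- vector("list", n)
  edge_seen <- new.env(parent = emptyenv())
  ekey <- function(i, j) paste(min(i, j), max(i, j))

  digit_str <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)

  emit <- function(u, parent, border) {
    visited[u] <<- TRUE
    parts <- element[u]
    # ring closures discovered at u (neighbor already visited, not parent edge)
    nb <- adj[[u]]
    children <- integer(0); ch_order <- integer(0)
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]; o <- nb[r, 2]
        key <- ekey(u, v)
        if (v == parent && is.null(edge_seen[[key]])) {
          edge_seen[[key]] <- TRUE
          next
        }
        if (!is.null(edge_seen[[key]])) next
        if (visited[v]) {
          edge_seen[[key]] <- TRUE
          ring_digit <<- ring_digit + 1L
          open_at[[v]] <<- c(open_at[[v]], ring_digit) # digit printed earlier
          parts <- paste0(parts, .mg_bond_char[o], digit_str(ring_digit))
        } else {
          children <- c(children, v); ch_order <- c(ch_order, o)
        }
      }
    }
    # note: digits opened at v were assigned when v was emitted later in text?
    # No: v is emitted before u, so its digits must be known at emit time.
    # Handled by two-pass assembly below.
    k <- length(children)
    if (k > 0L) {
      for (idx in seq_len(k)) {
        v <- children[idx]; o <- ch_order[idx]
        if (visited[v]) next # became visited through a cycle in this loop
        edge_seen[[ekey(u, v)]] <- TRUE
        sub <- emit(v, u, o)
        if (idx < k && any(!visited[children[(idx + 1):k]])) {
          parts <- paste0(parts, "(", .mg_bond_char[o], sub, ")")
        } else {
          parts <- paste0(parts, .mg_bond_char[o], sub)
        }
      }
    }
    parts
  }

  # Two passes: first to assign ring digits (so openings at earlier atoms are
  # known), then to assemble text with the digits in place.
  txt <- emit(1L, 0L, 0L)
  if (ring_digit == 0L) return(txt)

  # second pass with open_at populated
  visited <- logical(n)
  edge_seen <- new.env(parent = emptyenv())
  ring_digit <- 0L
  emit2 <- function(u, parent) {
    visited[u] <<- TRUE
    parts <- element[u]
    for (d in open_at[[u]]) parts <- paste0(parts, digit_str(d))
    nb <- adj[[u]]
    children <- integer(0); ch_order <- integer(0)
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]; o <- nb[r, 2]
        key <- ekey(u, v)
        if (v == parent && is.null(edge_seen[[key]])) {
          edge_seen[[key]] <- TRUE
          next
        }
        if (!is.null(edge_seen[[key]])) next
        if (visited[v]) {
          edge_seen[[key]] <- TRUE
          ring_digit <<- ring_digit + 1L
          parts <- paste0(parts, .mg_bond_char[o], digit_str(ring_digit))
        } else {
          children <- c(children, v); ch_order <- c(ch_order, o)
        }
      }
    }
    k <- length(children)
    if (k > 0L) {
      for (idx in seq_len(k)) {
        v <- children[idx]; o <- ch_order[idx]
        if (visited[v]) next
        edge_seen[[ekey(u, v)]] <- TRUE
        sub <- emit2(v, u)
        if (idx < k && any(!visited[children[(idx + 1):k]])) {
          parts <- paste0(parts, "(", .mg_bond_char[o], sub, ")")
        } else {
          parts <- paste0(parts, .mg_bond_char[o], sub)
        }
      }
    }
    parts
  }
  emit2(1L, 0L)
}

#' Decode SELFIES strings to SMILES
#'
#' Applies the derivation rules: bond orders are capped by remaining valence,
#' branches and rings carry explicit length/distance index tokens, and tokens
#' that cannot be applied are skipped. Consequently decoding never fails on
#' any ordering of alphabet tokens — the robustness guarantee behind the
#' generator's Valid = 1 metric. A string with no applicable atom token
#' decodes to `""`, the empty molecule (which the toolkit parses as the
#' zero-atom molecule).
#'
#' The only error condition is a token outside the alphabet (see
#' [selfies_alphabet()]).
#'
#' @param selfies Character vector of SELFIES strings.
#' @return Character vector of SMILES strings.
#' @export
#' @examples
#' selfies_to_smiles("[C][C][O]")
#' selfies_to_smiles("[C][=C][C][=C][C][=C][Ring2][C][#C]")
selfies_to_smiles <- function(selfies) {
  vapply(selfies, function(s) {
    st <- .mg_new_state()
    .mg_derive(split_selfies(s), st, 0L)
    .mg_write_smiles(st$element, st$bonds)
  }, character(1), USE.NAMES = FALSE)
}

# --- graph -> SELFIES encoder ------------------------------------------------

.mg_encode_graph <- function(atoms, bonds) {
  n <- length(atoms)
  if (n == 0L) return("")
  adj <- vector("list", n)
  if (length(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1] + 1L; j <- bonds[r, 2] + 1L; o <- bonds[r, 3]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  ord <- integer(n) # emission (= decoder creation) order
  counter <- 0L
  edge_done <- new.env(parent = emptyenv())
  ekey <- function(i, j) paste(min(i, j), max(i, j))

  index_tokens <- function(q, one, two) {
    if (q <= 15L) {
      c(one, .mg_index_alphabet[q + 1L])
    } else if (q <= 255L) {
      c(two, .mg_index_alphabet[q %/% 16L + 1L],
        .mg_index_alphabet[q %% 16L + 1L])
    } else {
      stop("molecule too large for the codec (branch/ring index > 255)")
    }
  }

  encode_from <- function(u, parent, border) {
    counter <<- counter + 1L
    ord[u] <<- counter
    out <- paste0("[", .mg_bond_char[border], atoms[u], "]")
    nb <- adj[[u]]
    children <- integer(0); ch_order <- integer(0)
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]; o <- nb[r, 2]
        key <- ekey(u, v)
        if (!is.null(edge_done[[key]])) next
        if (ord[v] > 0L) { # ring closure: v already emitted
          edge_done[[key]] <- TRUE
          q <- ord[u] - ord[v] - 1L
          pre <- c("", "=", "#")[o]
          out <- c(out, index_tokens(q, paste0("[", pre, "Ring1]"),
                                     paste0("[", pre, "Ring2]")))
        } else {
          children <- c(children, v); ch_order <- c(ch_order, o)
        }
      }
    }
    k <- length(children)
    if (k > 0L) {
      for (idx in seq_len(k)) {
        v <- children[idx]; o <- ch_order[idx]
        if (ord[v] > 0L) next # reached through a ring during this loop
        edge_done[[ekey(u, v)]] <- TRUE
        sub <- encode_from(v, u, o)
        remaining <- if (idx < k) any(ord[children[(idx + 1):k]] == 0L) else FALSE
        if (remaining) {
          out <- c(out, index_tokens(length(sub) - 1L, "[Branch1]", "[Branch2]"),
                   sub)
        } else {
          out <- c(out, sub)
        }
      }
    }
    out
  }

  toks <- encode_from(1L, 0L, 1L)
  paste(toks, collapse = "")
}

#' Encode SMILES as SELFIES
#'
#' Converts each molecule to a kekulized, stereochemistry-free graph through
#' the cheminformatics backend, then writes SELFIES tokens by depth-first
#' traversal (branches with explicit length tokens, rings with distance
#' tokens). Decoding the result reproduces the input molecule up to canonical
#' SMILES equality.
#'
#' The codec covers neutral organic-subset molecules (B, C, N, O, F, P, S,
#' Cl, Br, I; bond orders 1-3). Charged atoms, isotopes and radicals raise an
#' error naming the offending record; stereochemistry is stripped.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of SELFIES strings.
#' @export
#' @examples
#' \dontrun{
#' smiles_to_selfies(c("C", "CCO", "C1=CC=CC=C1"))
#' }
smiles_to_selfies <- function(smiles) {
  graphs <- chem_graphs(smiles)
  vapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    if (!identical(g$ok, 1L) && !identical(g$ok, 1)) {
      stop("cannot encode record ", i, " ('", smiles[i], "'): ", g$err,
           call. = FALSE)
    }
    bonds <- g$bonds
    if (is.null(bonds) || length(bonds) == 0L) {
      bonds <- matrix(integer(), ncol = 3)
    } else if (!is.matrix(bonds)) {
      bonds <- matrix(unlist(bonds), ncol = 3, byrow = TRUE)
    }
    .mg_encode_graph(g$atoms, bonds)
  }, character(1))
}

# --- vocabulary and tokenization --------------------------------------------

#' Build a token vocabulary from a SELFIES corpus
#'
#' The vocabulary is the sorted set of chemical tokens occurring in the
#' corpus, preceded by the three special tokens at fixed indices: SOS = 1,
#' EOS = 2, PAD = 3 (R is 1-based). Sorting uses radix order, so the result
#' is byte-stable across locales and process restarts.
#'
#' @param corpus Character vector of SELFIES strings (nonempty).
#' @return An object of class `mg_vocab` with fields `tokens` (full token
#'   vector including specials), `specials` (named indices) and `n`.
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(is.character(corpus))
  if (length(corpus) == 0L) stop("cannot build a vocabulary from an empty corpus")
  chem <- sort(unique(unlist(lapply(corpus, split_selfies))), method = "radix")
  if (length(chem) == 0L) stop("corpus contains no tokens")
  specials <- c(SOS = 1L, EOS = 2L, PAD = 3L)
  structure(
    list(tokens = c("<SOS>", "<EOS>", "<PAD>", chem),
         specials = specials,
         n = length(chem) + 3L),
    class = "mg_vocab"
  )
}

#' @export
print.mg_vocab <- function(x, ...) {
  cat("<mg_vocab> ", x$n, " tokens (", x$n - 3L, " chemical + SOS/EOS/PAD)\n",
      sep = "")
  invisible(x)
}

token_to_index <- function(vocab, tokens) {
  idx <- match(tokens, vocab$tokens)
  if (anyNA(idx)) {
    stop("token(s) not in vocabulary: ",
         paste(unique(tokens[is.na(idx)]), collapse = ", "))
  }
  idx
}

index_to_token <- function(vocab, indices) {
  if (any(indices < 1L | indices > vocab$n)) {
    stop("token index out of range for vocabulary of size ", vocab$n)
  }
  vocab$tokens[indices]
}

#' Tokenize SELFIES strings to index sequences
#'
#' @param selfies Character vector of SELFIES strings.
#' @param vocab An `mg_vocab` from [build_vocabulary()].
#' @param add_specials Wrap each sequence as SOS + tokens + EOS.
#' @return List of integer vectors. [detokenize()] inverts exactly.
#' @export
tokenize <- function(selfies, vocab, add_specials = TRUE) {
  stopifnot(inherits(vocab, "mg_vocab"))
  lapply(selfies, function(s) {
    idx <- token_to_index(vocab, split_selfies(s))
    if (add_specials) c(vocab$specials[["SOS"]], idx, vocab$specials[["EOS"]])
    else idx
  })
}

#' @rdname tokenize
#' @param indices Integer vector of vocabulary indices.
#' @export
detokenize <- function(indices, vocab) {
  stopifnot(inherits(vocab, "mg_vocab"))
  toks <- index_to_token(vocab, indices)
  paste(toks[!toks %in% c("<SOS>", "<EOS>", "<PAD>")], collapse = "")
}

#' Serialize / read a vocabulary as JSON
#'
#' @param vocab An `mg_vocab`.
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "mg_vocab"))
  jsonlite::write_json(
    list(tokens = vocab$tokens, specials = as.list(vocab$specials)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(tokens = raw$tokens,
         specials = vapply(raw$specials, as.integer, integer(1)),
         n = length(raw$tokens)),
    class = "mg_vocab"
  )
}

#' Read a molecule list from disk
#'
#' Accepts either plain text (one SMILES per line) or CSV with a `smiles`
#' column and optional `target` (0 = no target) and `pxc50` columns; UTF-8.
#'
#' @param path File path (`.csv` is dispatched on extension).
#' @return Tibble with columns `smiles`, `target` and any further columns
#'   present in a CSV input.
#' @export
read_molecules <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    out <- tibble::as_tibble(utils::read.csv(path))
    if (!"smiles" %in% names(out)) {
      stop("CSV molecule file must have a `smiles` column: ", path)
    }
    if (!"target" %in% names(out)) out$target <- 0L
    out$target <- as.integer(out$target)
    out
  } else {
    lines <- trimws(readLines(path, encoding = "UTF-8"))
    tibble::tibble(smiles = lines[nzchar(lines)], target = 0L)
  }
}

vocab_hash <- function(vocab) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(vocab$tokens, tmp)
  unname(tools::md5sum(tmp))
}
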