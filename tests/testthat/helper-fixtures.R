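# Shared test helpers: an independent brute-force formula enumerator used
# as oracle, random formula/tree generators, and small builders for
# hand-made trees.

ATOMIC <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
            P = 30.97376163, S = 31.97207100)
EMASS <- 0.00054857990946

# Brute-force candidate enumeration: plain nested loops with mass pruning,
# written independently of the package's vectorised grid search. Returns
# sorted efp_token strings.
oracle_enumerate <- function(target_mz, polarity = 1L, tol_ppm = 6,
                             element_max = c(C = 39, H = 72, N = 20, O = 20,
                                             P = 9, S = 10),
                             cap = NULL, ratio_rules = TRUE,
                             rdbe_non_integer = TRUE) {
  tol <- tol_ppm * 1e-6 * target_mz
  lo <- target_mz - tol + polarity * EMASS
  hi <- target_mz + tol + polarity * EMASS
  lim <- function(el) {
    m <- min(element_max[[el]], floor(hi / ATOMIC[[el]]))
    if (!is.null(cap)) m <- min(m, cap[[el]])
    m
  }
  hits <- character()
  for (C in 0:lim("C")) { mC <- C * ATOMIC[["C"]]; if (mC > hi) break
    for (N in 0:lim("N")) { mN <- mC + N * ATOMIC[["N"]]; if (mN > hi) break
      for (O in 0:lim("O")) { mO <- mN + O * ATOMIC[["O"]]; if (mO > hi) break
        for (P in 0:lim("P")) { mP <- mO + P * ATOMIC[["P"]]; if (mP > hi) break
          for (S in 0:lim("S")) { mS <- mP + S * ATOMIC[["S"]]; if (mS > hi) break
            Hlo <- max(0, ceiling((lo - mS) / ATOMIC[["H"]]))
            Hhi <- min(lim("H"), floor((hi - mS) / ATOMIC[["H"]]))
            if (Hlo > Hhi) next
            for (H in Hlo:Hhi) {
              r <- C + 1 - H / 2 + (N + P) / 2
              if (rdbe_non_integer && (r %% 1 != 0.5 || r < -0.5)) next
              if (ratio_rules && C > 0) {
                if (H / C < 0.1 || H / C > 6 || N / C > 4 || O / C > 3 ||
                    P / C > 2 || S / C > 3) next
              }
              v <- c(C = C, H = H, N = N, O = O, P = P, S = S)
              v <- v[v > 0]
              hits <- c(hits, paste0(names(v), v, collapse = ""))
            }
          }
        }
      }
    }
  }
  sort(hits)
}

# Random valid elemental formula (even-electron-ion-like not enforced)
random_formula <- function() {
  elemental_formula(C = sample(0:12, 1), H = sample(0:20, 1), N = sample(0:4, 1),
                    O = sample(0:6, 1), P = sample(0:2, 1), S = sample(0:2, 1))
}

# Random ground-truth tree whose every node is assignable under the default
# constraints: root with odd H (half-integer RDBE), even-H/N/P-free losses
# preserve the parity, branching capped at 3 (within every top-N), relative
# intensities >= 50 so the DDA never drops a branch.
LOSSES <- c("H2O", "CO", "CO2", "CH2O", "C2H4", "C2H2O", "C3H6", "C2H4O2",
            "C2H6", "H2", "C4H8", "C2H4O")

random_truth_tree <- function(n_nodes = 12, max_depth = 5L, polarity = 1L) {
  N <- sample(0:2, 1)
  # H - N odd, so the ion RDBE sits on the half-integer grid
  root <- elemental_formula(C = sample(10:16, 1),
                            H = sample(c(17, 19, 21), 1) + (N %% 2),
                            N = N, O = sample(2:6, 1), S = sample(0:1, 1))
  root_tok <- serialize_formula(root, "efp_token")
  efps <- root_tok
  depth <- 1L
  kids <- integer(1)
  rel <- 100
  tries <- 0L
  while (length(efps) < n_nodes && tries < 500L) {
    tries <- tries + 1L
    i <- sample.int(length(efps), 1)
    if (depth[i] >= max_depth || kids[i] >= 3L) next
    parent <- parse_formula(sub(".*\\|\\|", "", efps[i]))
    loss <- parse_formula(sample(LOSSES, 1))
    if (!is_subformula(loss, parent)) next
    child <- subtract_formula(parent, loss)
    cc <- unclass(child)
    if (cc[["C"]] < 1 || cc[["H"]] < 1) next
    if (!passes_ratio_rules(child)) next
    r <- rdbe(child)
    if (r %% 1 != 0.5 || r < -0.5) next
    efp <- paste(efps[i], serialize_formula(child, "efp_token"), sep = "||")
    if (efp %in% efps) next
    kids[i] <- kids[i] + 1L
    efps <- c(efps, efp)
    depth <- c(depth, depth[i] + 1L)
    kids <- c(kids, 0L)
    rel <- c(rel, if (kids[i] == 1L) 100 else sample(50:95, 1))
  }
  truth_from_paths(efps, rel, polarity = polarity)
}

# Minimal fragmentation_tree-shaped object for consensus tests
fake_ftree <- function(efps, rel = NULL, root = "R1") {
  if (is.null(rel)) rel <- rep(100, length(efps))
  efps <- c(root, efps)
  rel <- c(100, rel)
  structure(
    list(nodes = data.frame(
      efp = efps,
      ms_level = lengths(strsplit(efps, "||", fixed = TRUE)),
      rel_intensity = rel, ppm_error = 0, stringsAsFactors = FALSE),
      root_token = root, polarity = 1L, compound_id = "",
      constraints = formula_constraints(), log = character()),
    class = "fragmentation_tree"
  )
}

# Hand-written minimal mzXML (network-order 64-bit peak arrays), bypassing
# the package writer so the reader is checked against the format itself.
write_minimal_mzxml <- function(path, scans) {
  enc <- function(p) jsonlite::base64_enc(writeBin(as.numeric(t(p)), raw(),
                                                   size = 8, endian = "big"))
  scan_xml <- vapply(scans, function(s) {
    pk <- s$peaks
    prec <- if (!is.null(s$precursor_mz)) {
      sprintf('<precursorMz precursorScanNum="%s" precursorIntensity="1000">%.6f</precursorMz>',
              s$precursor_scan_id, s$precursor_mz)
    } else ""
    sprintf(paste0(
      '<scan num="%s" msLevel="%d" peaksCount="%d" polarity="+" retentionTime="PT%sS" ',
      'lowMz="%f" highMz="%f" basePeakMz="%f" basePeakIntensity="%f" totIonCurrent="%f">\n',
      '%s<peaks precision="64" byteOrder="network" contentType="m/z-int" ',
      'compressionType="none" compressedLen="0">%s</peaks>\n</scan>'),
      s$scan_id, s$ms_level, nrow(pk), s$scan_id, min(pk$mz), max(pk$mz),
      pk$mz[which.max(pk$intensity)], max(pk$intensity), sum(pk$intensity),
      prec, enc(as.matrix(pk[c("mz", "intensity")]))
    )
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">\n',
    sprintf('<msRun scanCount="%d">\n', length(scans)),
    paste(scan_xml, collapse = "\n"), "\n</msRun>\n</mzXML>\n"
  )
  writeLines(xml, path)
  path
}
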