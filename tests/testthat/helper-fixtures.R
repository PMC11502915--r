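# Shared fixture builders; everything is generated in code at test time.

balancedGenConfig <- function(prev = 0.25) {
  generatorConfig(prevalence = rep(prev, 8))
}

smallCaseSet <- function(n = 8, seed = 42, prev = 0.25) {
  buildCaseSet(n, balancedGenConfig(prev), labelerPanelConfig(), seed = seed)
}

stdCaseSet <- function(n = 8, seed = 42, prev = 0.25) {
  preprocessCases(smallCaseSet(n, seed, prev), preprocessConfig("test"))
}

# brute-force ROC AUC by pairwise comparison (ties counted half)
bruteAuc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  num <- 0
  for (a in sp) for (b in sn) num <- num + (a > b) + 0.5 * (a == b)
  num / (length(sp) * length(sn))
}

# pixel-mask oracle for box-set IoU (rasterizes onto an integer grid)
maskIoU <- function(pred, ref, h = 200, w = 200) {
  rast <- function(boxes) {
    m <- matrix(FALSE, h, w)
    for (i in seq_len(NROW(boxes))) {
      r <- (floor(boxes$row0[i]) + 1):ceiling(boxes$row1[i])
      c <- (floor(boxes$col0[i]) + 1):ceiling(boxes$col1[i])
      m[r, c] <- TRUE
    }
    m
  }
  mp <- rast(pred); mr <- rast(ref)
  sum(mp & mr) / sum(mp | mr)
}

# independent 4-connected component labeling (breadth-first flood fill)
floodLabel <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% nrow(mask) + 1L; c <- (cur - 1L) %/% nrow(mask) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask)) {
          idx <- (cc - 1L) * nrow(mask) + rr
          if (mask[idx] && lab[idx] == 0L) { lab[idx] <- nxt; queue <- c(queue, idx) }
        }
      }
    }
  }
  lab
}

# minimal single-frame explicit-VR little-endian DICOM byte stream
makeDicomBytes <- function(img16, photometric = "MONOCHROME2") {
  rows <- nrow(img16); cols <- ncol(img16)
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  elem <- function(group, el, vr, value) {
    if (vr %in% c("OB", "OW")) {
      c(u16(group), u16(el), charToRaw(vr), as.raw(c(0, 0)), u32(length(value)), value)
    } else {
      if (length(value) %% 2 == 1) value <- c(value, as.raw(0x20))
      c(u16(group), u16(el), charToRaw(vr), u16(length(value)), value)
    }
  }
  ts <- charToRaw("1.2.840.10008.1.2.1")
  if (length(ts) %% 2 == 1) ts <- c(ts, as.raw(0))
  meta <- elem(2L, 0x0010, "UI", ts)
  body <- c(
    elem(0x0028, 0x0004, "CS", charToRaw(photometric)),
    elem(0x0028, 0x0010, "US", u16(rows)),
    elem(0x0028, 0x0011, "US", u16(cols)),
    elem(0x0028, 0x0100, "US", u16(16L)),
    elem(0x0028, 0x0103, "US", u16(0L)),
    elem(0x7fe0, 0x0010, "OW",
         writeBin(as.integer(t(img16)), raw(), size = 2, endian = "little")))
  c(raw(128), charToRaw("DICM"), meta, body)
}
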