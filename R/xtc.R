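# Native reader for GROMACS XTC trajectories.
#
# XTC is an XDR (big-endian) stream of frames; coordinates are stored in nm
# with the lossy "3dfcoord" integer compression for systems of more than 9
# atoms (plain floats otherwise). This file ports that decompression scheme.
# Returned coordinates are in nm; callers convert to Angstrom.

.xtc_magic <- 1995L

.magicints <- c(
  0, 0, 0, 0, 0, 0, 0, 0, 0, 8, 10, 12, 16, 20, 25, 32, 40, 50, 64,
  80, 101, 128, 161, 203, 256, 322, 406, 512, 645, 812, 1024, 1290,
  1625, 2048, 2580, 3250, 4096, 5060, 6501, 8192, 10321, 13003, 16384,
  20642, 26007, 32768, 41285, 52015, 65536, 82570, 104031, 131072,
  165140, 208063, 262144, 330280, 416127, 524287, 660561, 832255,
  1048576, 1321122, 1664510, 2097152, 2642245, 3329021, 4194304,
  5284491, 6658042, 8388607, 10568983, 13316085, 16777216)
.firstidx <- 9L  # 0-based index of the first non-zero magicint (value 8)

# bits needed so that 2^bits > size
xtc_sizeofint <- function(size) {
  n <- 0L
  num <- 1
  while (size >= num && n < 32L) {
    n <- n + 1L
    num <- num * 2
  }
  n
}

# total bits needed to encode a triple with the given per-axis sizes,
# computed via byte-wise big-number multiplication (exact port)
xtc_sizeofints <- function(sizes) {
  bytes <- c(1, numeric(31))
  num_of_bytes <- 1L
  for (i in seq_along(sizes)) {
    tmp <- 0
    for (bytecnt in seq_len(num_of_bytes)) {
      tmp <- bytes[bytecnt] * sizes[i] + tmp
      bytes[bytecnt] <- tmp %% 256
      tmp <- tmp %/% 256
    }
    while (tmp != 0) {
      num_of_bytes <- num_of_bytes + 1L
      bytes[num_of_bytes] <- tmp %% 256
      tmp <- tmp %/% 256
    }
  }
  num <- 1
  num_of_bytes <- num_of_bytes - 1L
  num_of_bits <- 0L
  while (bytes[num_of_bytes + 1L] >= num) {
    num_of_bits <- num_of_bits + 1L
    num <- num * 2
  }
  num_of_bits + num_of_bytes * 8L
}

# mutable bit-stream state over a byte vector (values 0..255)
xtc_bitstate <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes
  env$cnt <- 1L
  env$lastbits <- 0L
  env$lastbyte <- 0
  env
}

xtc_decodebits <- function(st, nbits) {
  total <- nbits
  num <- 0
  lastbyte <- st$lastbyte
  lastbits <- st$lastbits
  cnt <- st$cnt
  bytes <- st$bytes
  while (nbits >= 8L) {
    lastbyte <- (lastbyte %% 2^lastbits) * 256 + bytes[cnt]
    cnt <- cnt + 1L
    num <- num + (lastbyte %/% 2^lastbits) * 2^(nbits - 8L)
    nbits <- nbits - 8L
  }
  if (nbits > 0L) {
    if (lastbits < nbits) {
      lastbyte <- (lastbyte %% 2^lastbits) * 256 + bytes[cnt]
      cnt <- cnt + 1L
      lastbits <- lastbits + 8L
    }
    lastbits <- lastbits - nbits
    num <- num + (lastbyte %/% 2^lastbits) %% 2^nbits
  }
  num <- num %% 2^total
  st$lastbyte <- lastbyte %% 2^lastbits
  st$lastbits <- lastbits
  st$cnt <- cnt
  num
}

# read num_of_bits from the stream and split them into a triple by
# big-number division with the given sizes
xtc_decodeints <- function(st, num_of_bits, sizes) {
  bytes_ <- numeric(32)
  nb <- 0L
  while (num_of_bits > 8L) {
    nb <- nb + 1L
    bytes_[nb] <- xtc_decodebits(st, 8L)
    num_of_bits <- num_of_bits - 8L
  }
  if (num_of_bits > 0L) {
    nb <- nb + 1L
    bytes_[nb] <- xtc_decodebits(st, num_of_bits)
  }
  nums <- numeric(3)
  for (i in 3:2) {
    num <- 0
    for (j in nb:1) {
      num <- num * 256 + bytes_[j]
      p <- num %/% sizes[i]
      bytes_[j] <- p
      num <- num - p * sizes[i]
    }
    nums[i] <- num
  }
  nums[1] <- bytes_[1] + bytes_[2] * 256 + bytes_[3] * 65536 + bytes_[4] * 16777216
  nums
}

xtc_decompress_frame <- function(con, natoms) {
  precision <- readBin(con, "numeric", n = 1, size = 4, endian = "big")
  minint <- readBin(con, "integer", n = 3, size = 4, endian = "big")
  maxint <- readBin(con, "integer", n = 3, size = 4, endian = "big")
  smallidx <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  nbytes <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  data <- readBin(con, "raw", n = nbytes)
  pad <- (4L - nbytes %% 4L) %% 4L
  if (pad > 0) readBin(con, "raw", n = pad)

  sizeint <- maxint - minint + 1
  if (max(sizeint) > 16777215) {
    bitsizeint <- vapply(sizeint, xtc_sizeofint, integer(1))
    bitsize <- 0L
  } else {
    bitsizeint <- c(0L, 0L, 0L)
    bitsize <- xtc_sizeofints(sizeint)
  }

  smaller <- .magicints[max(.firstidx, smallidx - 1L) + 1L] %/% 2
  smallnum <- .magicints[smallidx + 1L] %/% 2
  sizesmall <- rep(.magicints[smallidx + 1L], 3)
  inv_precision <- 1 / precision

  st <- xtc_bitstate(as.numeric(data))
  out <- numeric(3 * natoms)
  i <- 0L
  pos <- 0L
  run <- 0L
  while (i < natoms) {
    if (bitsize == 0L) {
      thiscoord <- c(xtc_decodebits(st, bitsizeint[1]),
                     xtc_decodebits(st, bitsizeint[2]),
                     xtc_decodebits(st, bitsizeint[3]))
    } else {
      thiscoord <- xtc_decodeints(st, bitsize, sizeint)
    }
    i <- i + 1L
    thiscoord <- thiscoord + minint
    prevcoord <- thiscoord

    # the flag marks a *change* in run length; when 0, the previous run
    # persists for this atom as well
    flag <- xtc_decodebits(st, 1L)
    is_smaller <- 0L
    if (flag == 1) {
      run <- xtc_decodebits(st, 5L)
      is_smaller <- run %% 3L
      run <- run - is_smaller
      is_smaller <- is_smaller - 1L
    }
    if (run > 0L) {
      for (k in seq(0L, run - 1L, by = 3L)) {
        thiscoord <- xtc_decodeints(st, smallidx, sizesmall)
        i <- i + 1L
        thiscoord <- thiscoord + prevcoord - smallnum
        if (k == 0L) {
          tmp <- thiscoord
          thiscoord <- prevcoord
          prevcoord <- tmp
          out[pos + 1:3] <- prevcoord * inv_precision
          pos <- pos + 3L
        } else {
          prevcoord <- thiscoord
        }
        out[pos + 1:3] <- thiscoord * inv_precision
        pos <- pos + 3L
      }
    } else {
      out[pos + 1:3] <- thiscoord * inv_precision
      pos <- pos + 3L
    }
    smallidx <- smallidx + is_smaller
    if (is_smaller < 0L) {
      smallnum <- smaller
      smaller <- if (smallidx > .firstidx) .magicints[smallidx] %/% 2 else 0
    } else if (is_smaller > 0L) {
      smaller <- smallnum
      smallnum <- .magicints[smallidx + 1L] %/% 2
    }
    sizesmall <- rep(.magicints[smallidx + 1L], 3)
  }
  out
}

# Read every frame of an XTC file. Returns an n_frames x (3 * n_atoms)
# matrix of coordinates in nm.
read_xtc_coords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  frames <- list()
  repeat {
    magic <- readBin(con, "integer", n = 1, size = 4, endian = "big")
    if (length(magic) == 0) break
    if (magic != .xtc_magic) {
      stop("not an XTC stream: bad magic number ", magic,
           " at frame ", length(frames) + 1)
    }
    natoms <- readBin(con, "integer", n = 1, size = 4, endian = "big")
    readBin(con, "integer", n = 1, size = 4, endian = "big")   # step
    readBin(con, "numeric", n = 1, size = 4, endian = "big")   # time
    readBin(con, "numeric", n = 9, size = 4, endian = "big")   # box
    size <- readBin(con, "integer", n = 1, size = 4, endian = "big")
    if (size != natoms) stop("corrupt XTC frame: size ", size,
                             " != natoms ", natoms)
    coords <- if (natoms <= 9) {
      readBin(con, "numeric", n = 3 * natoms, size = 4, endian = "big")
    } else {
      xtc_decompress_frame(con, natoms)
    }
    frames[[length(frames) + 1]] <- coords
  }
  if (length(frames) == 0) stop("no frames found in ", path)
  do.call(rbind, frames)
}
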