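/* Raw-deflate codec primitives used by the BGZF block writer.
 *
 * BGZF members carry a raw deflate stream (no zlib/gzip wrapper) framed by a
 * gzip header with a "BC" extra field and a CRC32/ISIZE trailer, so the codec
 * here is deflateInit2 with negative windowBits, plus crc32 over the
 * uncompressed payload.  Kept minimal on purpose: framing and block policy
 * live in R.
 */
#include <R.h>
#include <Rinternals.h>
#include <string.h>
#include <zlib.h>

SEXP C_deflate_raw(SEXP payload, SEXP level_)
{
    int level = asInteger(level_);
    if (level < 0 || level > 9)
        error("compression level must be in 0..9");
    uLong src_len = (uLong) XLENGTH(payload);

    z_stream zs;
    memset(&zs, 0, sizeof(zs));
    /* windowBits = -15: raw deflate; memLevel 8 and default strategy match
     * the zlib defaults so output is reproducible across runs. */
    int rc = deflateInit2(&zs, level, Z_DEFLATED, -15, 8, Z_DEFAULT_STRATEGY);
    if (rc != Z_OK)
        error("deflateInit2 failed (%d)", rc);

    uLong bound = deflateBound(&zs, src_len);
    SEXP out = PROTECT(allocVector(RAWSXP, (R_xlen_t) bound));
    zs.next_in = (Bytef *) RAW(payload);
    zs.avail_in = (uInt) src_len;
    zs.next_out = RAW(out);
    zs.avail_out = (uInt) bound;
    rc = deflate(&zs, Z_FINISH);
    if (rc != Z_STREAM_END) {
        deflateEnd(&zs);
        UNPROTECT(1);
        error("deflate failed (%d)", rc);
    }
    uLong out_len = bound - zs.avail_out;
    deflateEnd(&zs);

    SEXP trimmed = PROTECT(allocVector(RAWSXP, (R_xlen_t) out_len));
    memcpy(RAW(trimmed), RAW(out), out_len);
    UNPROTECT(2);
    return trimmed;
}

SEXP C_inflate_raw(SEXP data, SEXP isize_)
{
    /* isize: expected uncompressed length (from the BGZF ISIZE field). */
    double isize = asReal(isize_);
    if (isize < 0 || isize > 4294967295.0)
        error("invalid uncompressed size");
    SEXP out = PROTECT(allocVector(RAWSXP, (R_xlen_t) isize));

    z_stream zs;
    memset(&zs, 0, sizeof(zs));
    int rc = inflateInit2(&zs, -15);
    if (rc != Z_OK)
        error("inflateInit2 failed (%d)", rc);
    zs.next_in = (Bytef *) RAW(data);
    zs.avail_in = (uInt) XLENGTH(data);
    zs.next_out = RAW(out);
    zs.avail_out = (uInt) XLENGTH(out);
    rc = inflate(&zs, Z_FINISH);
    uLong got = (uLong) XLENGTH(out) - zs.avail_out;
    inflateEnd(&zs);
    if (rc != Z_STREAM_END || got != (uLong) isize) {
        UNPROTECT(1);
        error("inflate failed (rc=%d, got=%lu, expected=%.0f)",
              rc, (unsigned long) got, isize);
    }
    UNPROTECT(1);
    return out;
}

SEXP C_crc32(SEXP data)
{
    uLong crc = crc32(0L, Z_NULL, 0);
    crc = crc32(crc, (const Bytef *) RAW(data), (uInt) XLENGTH(data));
    return ScalarReal((double) crc);
}

static const R_CallMethodDef call_methods[] = {
    {"C_deflate_raw", (DL_FUNC) &C_deflate_raw, 2},
    {"C_inflate_raw", (DL_FUNC) &C_inflate_raw, 2},
    {"C_crc32",       (DL_FUNC) &C_crc32,       1},
    {NULL, NULL, 0}
};

void R_init_pipebam(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_methods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
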