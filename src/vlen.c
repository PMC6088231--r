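/* Variable-length (ragged) HDF5 datasets of doubles.
 *
 * rhdf5 maps R lists onto groups of scalar datasets, so the true HDF5
 * VLEN representation -- one dataset, one variable-length row per scan,
 * browsable as such in generic viewers -- is implemented here against
 * the HDF5 C API shipped in Rhdf5lib.  Only what the store needs:
 * create+write a whole column, read it back, and read a single row
 * (random access without touching the rest of the file).
 */
#include <R.h>
#include <Rinternals.h>
#include <hdf5.h>
#include <string.h>

static void h5err(const char *what, hid_t file)
{
    if (file >= 0) H5Fclose(file);
    error("HDF5 error in %s", what);
}

/* Create a chunked VLEN double dataset and write one row per list element.
 * gzip level 0 means no filter; shuffle is applied only when compressing. */
SEXP msh5_write_vlen(SEXP r_file, SEXP r_name, SEXP r_data, SEXP r_level,
                     SEXP r_shuffle)
{
    const char *fname = CHAR(STRING_ELT(r_file, 0));
    const char *dname = CHAR(STRING_ELT(r_name, 0));
    int level = asInteger(r_level);
    int shuffle = asLogical(r_shuffle);
    R_xlen_t n = XLENGTH(r_data);

    hid_t file = H5Fopen(fname, H5F_ACC_RDWR, H5P_DEFAULT);
    if (file < 0) error("cannot open HDF5 file '%s' for writing", fname);

    hid_t vtype = H5Tvlen_create(H5T_NATIVE_DOUBLE);
    hsize_t dims[1] = { (hsize_t)n };
    hid_t space = H5Screate_simple(1, dims, NULL);

    hid_t dcpl = H5Pcreate(H5P_DATASET_CREATE);
    if (n > 0) {
        hsize_t chunk[1] = { (hsize_t)(n < 1024 ? n : 1024) };
        H5Pset_chunk(dcpl, 1, chunk);
        if (level > 0) {
            if (shuffle) H5Pset_shuffle(dcpl);
            H5Pset_deflate(dcpl, (unsigned)level);
        }
    }

    hid_t dset = H5Dcreate2(file, dname, vtype, space, H5P_DEFAULT, dcpl,
                            H5P_DEFAULT);
    if (dset < 0) h5err("dataset creation", file);

    if (n > 0) {
        hvl_t *buf = (hvl_t *) R_alloc((size_t)n, sizeof(hvl_t));
        for (R_xlen_t i = 0; i < n; i++) {
            SEXP row = VECTOR_ELT(r_data, i);
            buf[i].len = (size_t) XLENGTH(row);
            buf[i].p = buf[i].len ? REAL(row) : NULL;
        }
        if (H5Dwrite(dset, vtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf) < 0)
            h5err("vlen write", file);
    }

    H5Pclose(dcpl);
    H5Dclose(dset);
    H5Sclose(space);
    H5Tclose(vtype);
    H5Fclose(file);
    return R_NilValue;
}

/* Read a full VLEN double dataset as a list of numeric vectors. */
SEXP msh5_read_vlen(SEXP r_file, SEXP r_name)
{
    const char *fname = CHAR(STRING_ELT(r_file, 0));
    const char *dname = CHAR(STRING_ELT(r_name, 0));

    hid_t file = H5Fopen(fname, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) error("cannot open HDF5 file '%s'", fname);
    hid_t dset = H5Dopen2(file, dname, H5P_DEFAULT);
    if (dset < 0) h5err("dataset open", file);

    hid_t space = H5Dget_space(dset);
    hsize_t dims[1];
    H5Sget_simple_extent_dims(space, dims, NULL);
    R_xlen_t n = (R_xlen_t) dims[0];

    hid_t vtype = H5Tvlen_create(H5T_NATIVE_DOUBLE);
    SEXP out = PROTECT(allocVector(VECSXP, n));
    if (n > 0) {
        hvl_t *buf = (hvl_t *) R_alloc((size_t)n, sizeof(hvl_t));
        if (H5Dread(dset, vtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf) < 0)
            h5err("vlen read", file);
        for (R_xlen_t i = 0; i < n; i++) {
            SEXP row = allocVector(REALSXP, (R_xlen_t) buf[i].len);
            SET_VECTOR_ELT(out, i, row);
            if (buf[i].len)
                memcpy(REAL(row), buf[i].p, buf[i].len * sizeof(double));
        }
        H5Dvlen_reclaim(vtype, space, H5P_DEFAULT, buf);
    }
    H5Tclose(vtype);
    H5Sclose(space);
    H5Dclose(dset);
    H5Fclose(file);
    UNPROTECT(1);
    return out;
}

/* Read a single row (1-based index) of a VLEN double dataset. */
SEXP msh5_read_vlen_row(SEXP r_file, SEXP r_name, SEXP r_index)
{
    const char *fname = CHAR(STRING_ELT(r_file, 0));
    const char *dname = CHAR(STRING_ELT(r_name, 0));
    hsize_t idx = (hsize_t) (asInteger(r_index) - 1);

    hid_t file = H5Fopen(fname, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) error("cannot open HDF5 file '%s'", fname);
    hid_t dset = H5Dopen2(file, dname, H5P_DEFAULT);
    if (dset < 0) h5err("dataset open", file);

    hid_t space = H5Dget_space(dset);
    hsize_t dims[1];
    H5Sget_simple_extent_dims(space, dims, NULL);
    if (idx >= dims[0]) {
        H5Sclose(space); H5Dclose(dset); H5Fclose(file);
        error("row index out of range");
    }

    hsize_t start[1] = { idx }, count[1] = { 1 };
    H5Sselect_hyperslab(space, H5S_SELECT_SET, start, NULL, count, NULL);
    hid_t mspace = H5Screate_simple(1, count, NULL);

    hid_t vtype = H5Tvlen_create(H5T_NATIVE_DOUBLE);
    hvl_t buf;
    if (H5Dread(dset, vtype, mspace, space, H5P_DEFAULT, &buf) < 0)
        h5err("vlen row read", file);

    SEXP out = PROTECT(allocVector(REALSXP, (R_xlen_t) buf.len));
    if (buf.len) memcpy(REAL(out), buf.p, buf.len * sizeof(double));
    H5Dvlen_reclaim(vtype, mspace, H5P_DEFAULT, &buf);

    H5Tclose(vtype);
    H5Sclose(mspace);
    H5Sclose(space);
    H5Dclose(dset);
    H5Fclose(file);
    UNPROTECT(1);
    return out;
}

/* Is the named dataset a variable-length dataset of doubles? */
SEXP msh5_is_vlen(SEXP r_file, SEXP r_name)
{
    const char *fname = CHAR(STRING_ELT(r_file, 0));
    const char *dname = CHAR(STRING_ELT(r_name, 0));

    hid_t file = H5Fopen(fname, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) error("cannot open HDF5 file '%s'", fname);
    hid_t dset = H5Dopen2(file, dname, H5P_DEFAULT);
    if (dset < 0) h5err("dataset open", file);
    hid_t type = H5Dget_type(dset);
    int ans = (H5Tget_class(type) == H5T_VLEN);
    H5Tclose(type);
    H5Dclose(dset);
    H5Fclose(file);
    return ScalarLogical(ans);
}
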