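#include <Rcpp.h>
#include <hdf5.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Thin wrappers around the HDF5 C API. Logical dimension 0 is rows,
// dimension 1 is columns; blocks cross the boundary to R in column-major
// order. Element types: integer/logical -> 32-bit int, double -> IEEE
// double, string -> variable-length UTF-8. A string attribute
// "element_type" on the dataset records the logical element type, since
// logical and integer share an on-disk type.

namespace {

struct H5Guard {
    // silence the default error stack once per process; errors surface as R
    // conditions instead
    H5Guard() { H5Eset_auto2(H5E_DEFAULT, NULL, NULL); }
};
static H5Guard guard_;

struct H5Mat {
    hid_t file = -1;
    hid_t dset = -1;
    hsize_t nrow = 0, ncol = 0;
    std::string elemtype;
    bool chunked = false;
    hsize_t chunk_rows = 0, chunk_cols = 0;
    ~H5Mat() {
        if (dset >= 0) H5Dclose(dset);
        if (file >= 0) H5Fclose(file);
    }
};

bool path_exists(const std::string& path) {
    FILE* f = fopen(path.c_str(), "rb");
    if (f) { fclose(f); return true; }
    return false;
}

hid_t vlen_str_type() {
    hid_t t = H5Tcopy(H5T_C_S1);
    H5Tset_size(t, H5T_VARIABLE);
    H5Tset_cset(t, H5T_CSET_UTF8);
    return t;
}

void write_elemtype_attr(hid_t dset, const std::string& elemtype) {
    hid_t atype = vlen_str_type();
    hid_t aspace = H5Screate(H5S_SCALAR);
    hid_t attr = H5Acreate2(dset, "element_type", atype, aspace,
                            H5P_DEFAULT, H5P_DEFAULT);
    const char* s = elemtype.c_str();
    H5Awrite(attr, atype, &s);
    H5Aclose(attr);
    H5Sclose(aspace);
    H5Tclose(atype);
}

std::string read_elemtype_attr(hid_t dset) {
    if (H5Aexists(dset, "element_type") <= 0) return "";
    hid_t attr = H5Aopen(dset, "element_type", H5P_DEFAULT);
    hid_t atype = H5Aget_type(attr);
    std::string out;
    if (H5Tis_variable_str(atype) > 0) {
        char* buf = NULL;
        hid_t mtype = vlen_str_type();
        if (H5Aread(attr, mtype, &buf) >= 0 && buf) {
            out = buf;
            free(buf);
        }
        H5Tclose(mtype);
    } else {
        size_t n = H5Tget_size(atype);
        std::vector<char> buf(n + 1, '\0');
        hid_t mtype = H5Tcopy(H5T_C_S1);
        H5Tset_size(mtype, n);
        if (H5Aread(attr, mtype, buf.data()) >= 0) out = buf.data();
        H5Tclose(mtype);
    }
    H5Tclose(atype);
    H5Aclose(attr);
    return out;
}

// open file + dataset, fill in an H5Mat (caller owns)
H5Mat* open_mat(const std::string& path, const std::string& dataset,
                bool readonly) {
    if (!path_exists(path)) stop("cannot open file '%s'", path.c_str());
    hid_t file = H5Fopen(path.c_str(),
                         readonly ? H5F_ACC_RDONLY : H5F_ACC_RDWR,
                         H5P_DEFAULT);
    if (file < 0) stop("'%s' is not a readable HDF5 file", path.c_str());
    if (H5Lexists(file, dataset.c_str(), H5P_DEFAULT) <= 0) {
        H5Fclose(file);
        stop("dataset '%s' not found in '%s'", dataset.c_str(), path.c_str());
    }
    hid_t dset = H5Dopen2(file, dataset.c_str(), H5P_DEFAULT);
    if (dset < 0) {
        H5Fclose(file);
        stop("dataset '%s' not found in '%s'", dataset.c_str(), path.c_str());
    }
    hid_t space = H5Dget_space(dset);
    int rank = H5Sget_simple_extent_ndims(space);
    if (rank != 2) {
        H5Sclose(space); H5Dclose(dset); H5Fclose(file);
        stop("dataset '%s' is not 2-dimensional", dataset.c_str());
    }
    hsize_t dims[2];
    H5Sget_simple_extent_dims(space, dims, NULL);
    H5Sclose(space);

    H5Mat* m = new H5Mat();
    m->file = file;
    m->dset = dset;
    m->nrow = dims[0];
    m->ncol = dims[1];

    hid_t dcpl = H5Dget_create_plist(dset);
    if (H5Pget_layout(dcpl) == H5D_CHUNKED) {
        hsize_t cd[2];
        H5Pget_chunk(dcpl, 2, cd);
        m->chunked = true;
        m->chunk_rows = cd[0];
        m->chunk_cols = cd[1];
    }
    H5Pclose(dcpl);

    m->elemtype = read_elemtype_attr(dset);
    if (m->elemtype.empty()) {
        hid_t dtype = H5Dget_type(dset);
        H5T_class_t cls = H5Tget_class(dtype);
        if (cls == H5T_INTEGER) m->elemtype = "integer";
        else if (cls == H5T_FLOAT) m->elemtype = "double";
        else if (cls == H5T_STRING) m->elemtype = "string";
        else {
            H5Tclose(dtype);
            delete m;
            stop("unsupported element type in dataset '%s'", dataset.c_str());
        }
        H5Tclose(dtype);
    }
    return m;
}

void check_block(const H5Mat& m, int row0, int nrows, int col0, int ncols) {
    if (row0 < 0 || col0 < 0 || nrows < 0 || ncols < 0 ||
        (hsize_t)(row0 + nrows) > m.nrow || (hsize_t)(col0 + ncols) > m.ncol) {
        stop("block [%d+%d, %d+%d] out of range for %d x %d dataset",
             row0, nrows, col0, ncols, (int)m.nrow, (int)m.ncol);
    }
}

hid_t select_block(const H5Mat& m, int row0, int nrows, int col0, int ncols) {
    hid_t fspace = H5Dget_space(m.dset);
    hsize_t start[2] = {(hsize_t)row0, (hsize_t)col0};
    hsize_t count[2] = {(hsize_t)nrows, (hsize_t)ncols};
    H5Sselect_hyperslab(fspace, H5S_SELECT_SET, start, NULL, count, NULL);
    return fspace;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_h5_create")]]
void cpp_h5_create(std::string path, std::string dataset,
                   int nrow, int ncol, std::string elemtype,
                   bool chunked, int chunk_rows, int chunk_cols,
                   int compress) {
    hid_t file;
    if (path_exists(path)) {
        file = H5Fopen(path.c_str(), H5F_ACC_RDWR, H5P_DEFAULT);
        if (file < 0) stop("'%s' exists but is not an HDF5 file", path.c_str());
        if (H5Lexists(file, dataset.c_str(), H5P_DEFAULT) > 0) {
            H5Fclose(file);
            stop("dataset '%s' already exists in '%s'",
                 dataset.c_str(), path.c_str());
        }
    } else {
        file = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
        if (file < 0) stop("cannot create file '%s'", path.c_str());
    }

    hid_t dtype;
    bool own_dtype = false;
    if (elemtype == "integer" || elemtype == "logical") {
        dtype = H5T_STD_I32LE;
    } else if (elemtype == "double") {
        dtype = H5T_IEEE_F64LE;
    } else if (elemtype == "string") {
        dtype = vlen_str_type();
        own_dtype = true;
    } else {
        H5Fclose(file);
        stop("unsupported element type '%s'", elemtype.c_str());
    }

    hsize_t dims[2] = {(hsize_t)nrow, (hsize_t)ncol};
    hid_t space = H5Screate_simple(2, dims, NULL);
    hid_t dcpl = H5Pcreate(H5P_DATASET_CREATE);
    if (chunked) {
        if (chunk_rows < 1 || chunk_cols < 1 ||
            chunk_rows > nrow || chunk_cols > ncol) {
            H5Pclose(dcpl); H5Sclose(space); H5Fclose(file);
            stop("chunk dimensions (%d, %d) exceed matrix dimensions (%d, %d)",
                 chunk_rows, chunk_cols, nrow, ncol);
        }
        hsize_t cd[2] = {(hsize_t)chunk_rows, (hsize_t)chunk_cols};
        H5Pset_chunk(dcpl, 2, cd);
        if (compress > 0) H5Pset_deflate(dcpl, compress);
    }
    hid_t dset = H5Dcreate2(file, dataset.c_str(), dtype, space,
                            H5P_DEFAULT, dcpl, H5P_DEFAULT);
    if (dset < 0) {
        H5Pclose(dcpl); H5Sclose(space); H5Fclose(file);
        stop("cannot create dataset '%s'", dataset.c_str());
    }
    write_elemtype_attr(dset, elemtype);
    H5Dclose(dset);
    H5Pclose(dcpl);
    H5Sclose(space);
    if (own_dtype) H5Tclose(dtype);
    H5Fclose(file);
}

// [[Rcpp::export(name = ".cpp_h5_open")]]
SEXP cpp_h5_open(std::string path, std::string dataset, bool readonly) {
    XPtr<H5Mat> xp(open_mat(path, dataset, readonly), true);
    return xp;
}

// [[Rcpp::export(name = ".cpp_h5_info")]]
List cpp_h5_info(SEXP handle) {
    XPtr<H5Mat> xp(handle);
    return List::create(
        _["nrow"] = (double)xp->nrow, _["ncol"] = (double)xp->ncol,
        _["elemtype"] = xp->elemtype, _["chunked"] = xp->chunked,
        _["chunk_rows"] = (double)xp->chunk_rows,
        _["chunk_cols"] = (double)xp->chunk_cols);
}

// [[Rcpp::export(name = ".cpp_h5_close")]]
void cpp_h5_close(SEXP handle) {
    XPtr<H5Mat> xp(handle);
    xp.release();
}

// Read a block, returned column-major as an R vector of length nrows*ncols.
// [[Rcpp::export(name = ".cpp_h5_read_block")]]
SEXP cpp_h5_read_block(SEXP handle, int row0, int nrows, int col0, int ncols) {
    XPtr<H5Mat> xp(handle);
    H5Mat& m = *xp;
    check_block(m, row0, nrows, col0, ncols);
    const R_xlen_t n = (R_xlen_t)nrows * ncols;
    hid_t fspace = select_block(m, row0, nrows, col0, ncols);
    hsize_t mdims[2] = {(hsize_t)nrows, (hsize_t)ncols};
    hid_t mspace = H5Screate_simple(2, mdims, NULL);

    SEXP out;
    if (m.elemtype == "double") {
        std::vector<double> buf(n);
        if (H5Dread(m.dset, H5T_NATIVE_DOUBLE, mspace, fspace, H5P_DEFAULT,
                    buf.data()) < 0) {
            H5Sclose(mspace); H5Sclose(fspace);
            stop("HDF5 read failed");
        }
        NumericVector v(n);
        for (int r = 0; r < nrows; ++r)
            for (int c = 0; c < ncols; ++c)
                v[(R_xlen_t)c * nrows + r] = buf[(R_xlen_t)r * ncols + c];
        out = v;
    } else if (m.elemtype == "integer" || m.elemtype == "logical") {
        std::vector<int> buf(n);
        if (H5Dread(m.dset, H5T_NATIVE_INT, mspace, fspace, H5P_DEFAULT,
                    buf.data()) < 0) {
            H5Sclose(mspace); H5Sclose(fspace);
            stop("HDF5 read failed");
        }
        if (m.elemtype == "integer") {
            IntegerVector v(n);
            for (int r = 0; r < nrows; ++r)
                for (int c = 0; c < ncols; ++c)
                    v[(R_xlen_t)c * nrows + r] = buf[(R_xlen_t)r * ncols + c];
            out = v;
        } else {
            LogicalVector v(n);
            for (int r = 0; r < nrows; ++r)
                for (int c = 0; c < ncols; ++c)
                    v[(R_xlen_t)c * nrows + r] = buf[(R_xlen_t)r * ncols + c];
            out = v;
        }
    } else {  // string
        std::vector<char*> buf(n, (char*)NULL);
        hid_t mtype = vlen_str_type();
        if (H5Dread(m.dset, mtype, mspace, fspace, H5P_DEFAULT,
                    buf.data()) < 0) {
            H5Tclose(mtype); H5Sclose(mspace); H5Sclose(fspace);
            stop("HDF5 read failed");
        }
        CharacterVector v(n);
        for (int r = 0; r < nrows; ++r) {
            for (int c = 0; c < ncols; ++c) {
                const char* s = buf[(R_xlen_t)r * ncols + c];
                v[(R_xlen_t)c * nrows + r] = s ? s : "";
            }
        }
        H5Dvlen_reclaim(mtype, mspace, H5P_DEFAULT, buf.data());
        H5Tclose(mtype);
        out = v;
    }
    H5Sclose(mspace);
    H5Sclose(fspace);
    return out;
}

// Write a column-major R vector of length nrows*ncols into a block.
// [[Rcpp::export(name = ".cpp_h5_write_block")]]
void cpp_h5_write_block(SEXP handle, int row0, int nrows, int col0, int ncols,
                        SEXP values) {
    XPtr<H5Mat> xp(handle);
    H5Mat& m = *xp;
    check_block(m, row0, nrows, col0, ncols);
    const R_xlen_t n = (R_xlen_t)nrows * ncols;
    if (Rf_xlength(values) != n) stop("value length does not match block size");
    hid_t fspace = select_block(m, row0, nrows, col0, ncols);
    hsize_t mdims[2] = {(hsize_t)nrows, (hsize_t)ncols};
    hid_t mspace = H5Screate_simple(2, mdims, NULL);
    herr_t status = -1;

    if (m.elemtype == "double") {
        NumericVector v(values);
        std::vector<double> buf(n);
        for (int r = 0; r < nrows; ++r)
            for (int c = 0; c < ncols; ++c)
                buf[(R_xlen_t)r * ncols + c] = v[(R_xlen_t)c * nrows + r];
        status = H5Dwrite(m.dset, H5T_NATIVE_DOUBLE, mspace, fspace,
                          H5P_DEFAULT, buf.data());
    } else if (m.elemtype == "integer" || m.elemtype == "logical") {
        IntegerVector v(values);
        std::vector<int> buf(n);
        for (int r = 0; r < nrows; ++r)
            for (int c = 0; c < ncols; ++c)
                buf[(R_xlen_t)r * ncols + c] = v[(R_xlen_t)c * nrows + r];
        status = H5Dwrite(m.dset, H5T_NATIVE_INT, mspace, fspace,
                          H5P_DEFAULT, buf.data());
    } else {
        CharacterVector v(values);
        std::vector<std::string> hold(n);
        std::vector<const char*> buf(n);
        for (int r = 0; r < nrows; ++r) {
            for (int c = 0; c < ncols; ++c) {
                hold[(R_xlen_t)r * ncols + c] =
                    as<std::string>(v[(R_xlen_t)c * nrows + r]);
                buf[(R_xlen_t)r * ncols + c] = hold[(R_xlen_t)r * ncols + c].c_str();
            }
        }
        hid_t mtype = vlen_str_type();
        status = H5Dwrite(m.dset, mtype, mspace, fspace, H5P_DEFAULT,
                          buf.data());
        H5Tclose(mtype);
    }
    H5Sclose(mspace);
    H5Sclose(fspace);
    if (status < 0) stop("HDF5 write failed");
}
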