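# Link against the HDF5 library that ships in the same prefix as this R
# installation (R_HOME = <prefix>/lib/R). Falls back to pkg-config if the
# prefix copy is absent.
HDF5_PREFIX = $(R_HOME)/../..
PKG_CPPFLAGS = -I$(HDF5_PREFIX)/include
PKG_LIBS = -L$(HDF5_PREFIX)/lib -Wl,-rpath,$(HDF5_PREFIX)/lib -lhdf5
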