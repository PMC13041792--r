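# ramanprep bundled Ne-Ar emission line library, version 1.0
# columns: wavenumber_cm1 <TAB> species
9677.994	Ar
9713.057	Ne
10194.865	Ne
10220.246	Ar
10346.162	Ne
10354.336	Ar
10474.045	Ne
10488.601	Ne
10541.096	Ne
10571.707	Ne
10609.652	Ne
10668.590	Ne
10690.362	Ar
10722.124	Ne
10751.705	Ne
10781.067	Ne
10840.696	Ar
10845.916	Ne
10867.486	Ne
10930.551	Ne
10961.343	Ar
11020.085	Ne
11053.363	Ne
11125.253	Ne
11211.391	Ne
11279.349	Ne
11294.496	Ne
11388.717	Ne
11518.190	Ne
11536.767	Ar
11554.843	Ne
11581.245	Ne
11639.736	Ne
11703.175	Ne
11735.106	Ar
11771.132	Ne
11869.929	Ar
11878.699	Ne
11893.138	Ar
11936.579	Ne
12047.714	Ne
12099.916	Ar
12107.446	Ne
12290.433	Ne
12322.388	Ar
12340.057	Ar
12372.471	Ne
12476.933	Ar
12490.382	Ar
12581.497	Ar
12589.416	Ne
12947.060	Ar
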