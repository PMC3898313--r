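<?xml version="1.0" encoding="UTF-8"?>
<!-- Plugin descriptor schema used by load_plugin_config(). This schema is
     defined by this package as a stand-in plugin-configuration dialect; it
     is not a claim about any external plugin system's real schema. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">
  <xs:element name="plugin">
    <xs:complexType>
      <xs:all>
        <xs:element name="input-slots" type="slotList" minOccurs="0"/>
        <xs:element name="output-slots" type="slotList" minOccurs="0"/>
        <xs:element name="environment" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="entry" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="name" type="xs:string" use="required"/>
                  <xs:attribute name="value" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="sdk" minOccurs="0">
          <xs:complexType>
            <xs:all>
              <xs:element name="fetch" type="xs:string" minOccurs="0"/>
              <xs:element name="push" type="xs:string" minOccurs="0"/>
            </xs:all>
          </xs:complexType>
        </xs:element>
        <xs:element name="error-management" type="xs:string" minOccurs="0"/>
      </xs:all>
      <xs:attribute name="id" type="xs:string" use="required"/>
      <xs:attribute name="type" use="required">
        <xs:simpleType>
          <xs:restriction base="xs:string">
            <xs:enumeration value="aligner"/>
            <xs:enumeration value="alignment-analysis"/>
            <xs:enumeration value="resource"/>
            <xs:enumeration value="artifact-install"/>
            <xs:enumeration value="task"/>
          </xs:restriction>
        </xs:simpleType>
      </xs:attribute>
    </xs:complexType>
  </xs:element>
  <xs:complexType name="slotList">
    <xs:sequence>
      <xs:element name="slot" minOccurs="0" maxOccurs="unbounded">
        <xs:complexType>
          <xs:attribute name="name" type="xs:string" use="required"/>
          <xs:attribute name="fileType" type="xs:string"/>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>
</xs:schema>
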